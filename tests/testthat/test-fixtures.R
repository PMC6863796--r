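test_that("scenario generation is deterministic and validates names", {
  expect_error(make_scenario("no-such-thing"), "tube-poiseuille")
  a <- make_scenario("curved-stented-14d", scale = 0.5, seed = 3)
  b <- make_scenario("curved-stented-14d", scale = 0.5, seed = 3)
  expect_identical(a, b)
  expect_equal(a$days, 14)
  expect_true(is.finite(a$vessel$curvature_radius))
  s <- make_scenario("straight-stented", scale = 0.5, seed = 3)
  expect_equal(s$days, 28)
  expect_false(is.finite(s$vessel$curvature_radius))
  # the curved and straight twins differ only in curvature
  expect_equal(s$vessel$lumen_radius, a$vessel$lumen_radius)
  expect_equal(s$vessel$segment_length, a$vessel$segment_length)
})

test_that("agent count scales with the cube of the vessel scale", {
  n_at <- function(scale) {
    cfg <- make_scenario("curved-stented-14d", scale = scale, seed = 1)
    nrow(build_vessel(cfg$vessel, equilibrate = FALSE))
  }
  ratio <- n_at(1.0) / n_at(0.5)
  expect_lt(abs(ratio / 8 - 1), 0.1)
})

test_that("scenario configs round-trip through YAML", {
  cfg <- make_scenario("straight-stented", scale = 0.4, seed = 9,
                       agent_scale = 1.5)
  path <- tempfile(fileext = ".yaml")
  write_scenario_yaml(cfg, path)
  cfg2 <- read_scenario_yaml(path)
  expect_equal(cfg2$name, cfg$name)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$vessel$agent_nominal_radius,
               cfg$vessel$agent_nominal_radius)
})

test_that("tube scenario supplies the flow-oracle geometry", {
  cfg <- make_scenario("tube-poiseuille", scale = 0.4, seed = 1)
  expect_equal(cfg$radius, 0.5)
  expect_equal(cfg$length, 2)
})
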