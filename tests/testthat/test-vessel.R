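test_that("local metric factor matches the toroidal definition", {
  vs <- tiny_vessel_spec()
  vc <- vessel_spec(lumen_radius = 1.5, segment_length = 6,
                    curvature_radius = 28)
  # straight vessel: identically 1
  expect_equal(local_metric_factor(cbind(0.4, -0.1, 2), vs), 1)
  # apex of the arc is at the origin with the outer curve toward -x:
  # +1 mm outward -> 29/28, +1 mm inward -> 27/28
  expect_equal(local_metric_factor(c(-1, 0, 0), vc), 29 / 28)
  expect_equal(local_metric_factor(c(1, 0, 0), vc), 27 / 28)
  expect_equal(local_metric_factor(c(0, 0.4, 0), vc), 1)
})

test_that("vessel spec validation rejects impossible geometry", {
  expect_error(vessel_spec(lumen_radius = 1.5, curvature_radius = 1.6),
               "self-intersecting")
  expect_error(vessel_spec(wall_layers = data.frame(
    kind = c("SMC", "EEL_SMC"), n = c(2L, 1L))), "innermost")
})

test_that("straight vessel: nominal radii, no overlap, layer order, equilibrium", {
  vs <- tiny_vessel_spec()
  raw <- build_vessel(vs, equilibrate = FALSE)
  # straight: scaling factor is identically 1
  expect_true(all(raw$r == vs$agent_nominal_radius))
  # zero-overlap at construction
  f <- net_forces(raw, mech_params())
  expect_gte(min(1 + f$strain_min), 0.99)
  # layer topology: radial bands are IEL -> SMC -> EEL
  pr <- stentsim:::centreline_project(vs, cbind(raw$x, raw$y, raw$z))
  expect_true(max(pr$rho[raw$kind == "IEL_SMC"]) <
                min(pr$rho[raw$kind == "SMC"]))
  expect_true(max(pr$rho[raw$kind == "SMC"]) <
                min(pr$rho[raw$kind == "EEL_SMC"]))
  # built vessel is in mechanical equilibrium
  v <- tiny_vessel()
  expect_true(attr(v, "converged"))
  expect_lt(equilibrium_residual(v, mech_params()), mech_params()$force_tol)
})

test_that("curved vessel: metric-scaled radii give a near-equilibrium build", {
  vs <- tiny_vessel_spec(curvature = 5)
  raw <- build_vessel(vs, equilibrate = FALSE)
  # rest radii follow the local metric factor
  expect_equal(raw$r,
               vs$agent_nominal_radius *
                 local_metric_factor(cbind(raw$x, raw$y, raw$z), vs),
               tolerance = 1e-12)
  # the scaled construction carries less misfit than nominal radii
  f_scaled <- net_forces(raw, mech_params())
  raw_u <- raw
  raw_u$r <- rep(vs$agent_nominal_radius, nrow(raw_u))
  f_unscaled <- net_forces(raw_u, mech_params())
  mag <- function(f) mean(sqrt(f$fx^2 + f$fy^2 + f$fz^2))
  expect_lt(mag(f_scaled), mag(f_unscaled))
  # and equilibrates to the same tolerance as the straight vessel
  v <- tiny_curved_vessel()
  expect_true(attr(v, "converged"))
  expect_lt(equilibrium_residual(v, mech_params()), mech_params()$force_tol)
})

test_that("agent IO round-trips through CSV and writes VTK", {
  v <- tiny_vessel()
  csv <- tempfile(fileext = ".csv")
  write_agents_csv(v, csv)
  v2 <- read_agents_csv(csv)
  expect_equal(nrow(v2), nrow(v))
  expect_equal(v2$x, v$x, tolerance = 1e-6)
  expect_equal(v2$kind, v$kind)
  vtk <- tempfile(fileext = ".vtk")
  write_agents_vtk(v, vtk)
  head <- readLines(vtk, n = 5)
  expect_match(head[4], "POLYDATA")
  expect_match(head[5], sprintf("POINTS %d", nrow(v)))
})
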