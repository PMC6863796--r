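test_that("zero horizon leaves the state unchanged", {
  dep <- small_deployment()
  st <- dep$state
  st2 <- run_growth(st, days = 0)
  expect_identical(st2$agents, st$agents)
  expect_equal(st2$time_h, st$time_h)
})

test_that("identical seeds give identical trajectories", {
  dep <- small_deployment()
  run_once <- function(seed) {
    set.seed(seed)
    run_growth(dep$state, days = 1, wss_override = 0.1)
  }
  a <- run_once(31); b <- run_once(31); c <- run_once(32)
  expect_identical(a$agents, b$agents)
  expect_identical(a$series, b$series)
  expect_false(identical(a$agents, c$agents))
})

test_that("checkpoint/restore round-trips and restarts bit-identically", {
  dep <- small_deployment()
  path <- tempfile(fileext = ".rds")

  set.seed(77)
  full <- run_growth(dep$state, days = 1, wss_override = 0.1)

  set.seed(77)
  half <- run_growth(dep$state, days = 0.5, wss_override = 0.1)
  checkpoint_state(half, path)
  # scramble the RNG to prove restore reinstates it
  runif(13)
  half2 <- restore_state(path)
  expect_identical(half2$agents, half$agents)
  resumed <- run_growth(half2, days = 0.5, wss_override = 0.1)
  expect_identical(resumed$agents, full$agents)
  expect_equal(resumed$time_h, full$time_h)

  # corrupted checkpoint is rejected explicitly
  bad <- tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bad)
  expect_error(restore_state(bad), "corrupt")
  saveRDS(list(version = 99L, state = NULL, rng = NULL), bad)
  expect_error(restore_state(bad), "version")
})

test_that("tissue only accumulates: agent counts never decrease", {
  dep <- small_deployment()
  set.seed(5)
  st <- run_growth(dep$state, days = 2, wss_override = 0.1)
  s <- st$series
  expect_true(all(diff(s$n_smc) >= 0))
  expect_true(all(diff(s$n_ecm) >= 0))
  expect_true(all(diff(s$coverage) >= 0))
  expect_gt(tail(s$n_smc, 1) + tail(s$n_ecm, 1),
            s$n_smc[1] + s$n_ecm[1])
})
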