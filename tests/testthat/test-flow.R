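test_that("voxelization matches analytic volumes and classifies the lumen", {
  # single sphere: wall voxel count within 5% of its volume
  vox <- stentsim:::cpp_voxelize(0, 0, 0, 0.15, -0.2, -0.2, -0.2,
                                 0.03, 14L, 14L, 14L)
  expected <- 4 / 3 * pi * 0.15^3 / 0.03^3
  expect_lt(abs(sum(vox$flags) - expected) / expected, 0.05)

  # empty agent set: all fluid
  vox0 <- stentsim:::cpp_voxelize(numeric(0), numeric(0), numeric(0),
                                  numeric(0), 0, 0, 0, 0.03, 5L, 5L, 5L)
  expect_true(all(vox0$flags == 0L))

  # concentric cylinder: the lumen is one connected fluid region
  lat <- tube_lattice(0.3, 0.9, 0.03)
  centre <- which(array(lat$lumen, lat$dims)[ , , 2], arr.ind = TRUE)[1, ]
  seed <- as.integer((1 * lat$dims[2] + (centre[2] - 1)) * lat$dims[1] +
                       centre[1] - 1)
  reach <- stentsim:::cpp_flood(lat$flags, lat$dims[1], lat$dims[2],
                                lat$dims[3], seed)
  # flood from one lumen cell reaches every interior lumen cell
  expect_equal(sum(reach), sum(lat$flags == 0L))

  # vessel voxelization: leaky wall is rejected with coordinates
  v <- tiny_vessel()
  vs <- attr(v, "vessel_spec")
  holed <- v[!(v$y > 0.1 & abs(v$z) < 0.1), ]
  attr(holed, "vessel_spec") <- vs
  expect_error(voxelize(holed, vs, 0.03), "leak")
})

test_that("tube flow reproduces the Poiseuille solution", {
  fp <- flow_params()
  lat <- small_tube()   # radius 0.3 mm, voxel 30 um
  expect_true(lat$converged)
  expect_gt(lat$tau, 0.5)
  expect_lt(lat$tau, 2)
  dims <- lat$dims
  R <- 0.3
  U <- lat$inlet_flow / (pi * R^2)
  uz <- array(lat$velocity$uz, dims)
  mid <- dims[3] %/% 2
  # centreline velocity = 2 U
  expect_lt(abs(max(uz[, , mid]) / (2 * U) - 1), 0.03)
  # wall WSS = 4 mu U / R, uniform over the wall
  w <- array(lat$wss, dims)
  wv <- w[, , (mid - 4):(mid + 4)]
  wv <- wv[wv > 0]
  wan <- 4 * fp$viscosity * (U * 1e-3) / (R * 1e-3)
  expect_lt(abs(mean(wv) / wan - 1), 0.05)
  expect_lt(sd(wv) / mean(wv), 0.05)
  # mass conservation: inlet and outlet flux within 1%
  flux_in <- sum(uz[, , 2])
  flux_out <- sum(uz[, , dims[3] - 1])
  expect_lt(abs(flux_out / flux_in - 1), 0.01)
})

test_that("zero inlet flow gives a quiescent lattice", {
  lat <- tube_lattice(0.2, 0.4, 0.04)
  lat <- solve_flow(lat, flow_params(inlet_velocity = 0))
  expect_true(all(lat$velocity$uz == 0))
  expect_true(all(lat$wss == 0))
})

test_that("grid refinement moves tube WSS toward the closed form", {
  fp <- flow_params()
  err <- sapply(c(0.06, 0.03), function(h) {
    lat <- solve_flow(tube_lattice(0.3, 0.6, h), fp)
    dims <- lat$dims
    U <- lat$inlet_flow / (pi * 0.3^2)
    wan <- 4 * fp$viscosity * (U * 1e-3) / (0.3 * 1e-3)
    mid <- dims[3] %/% 2
    w <- array(lat$wss, dims)
    wv <- w[, , (mid - 2):(mid + 2)]
    abs(mean(wv[wv > 0]) / wan - 1)
  })
  expect_lt(err[2], err[1])
})

test_that("WSS maps back to lumen-facing agents only", {
  fp <- flow_params()
  v <- tiny_vessel()
  vs <- attr(v, "vessel_spec")
  lat <- voxelize(v, vs, 0.03)
  lat <- solve_flow(lat, fp)
  a2 <- map_wss_to_agents(lat, v)
  pr <- stentsim:::centreline_project(vs, cbind(a2$x, a2$y, a2$z))
  inner <- a2$kind == "IEL_SMC"
  # surface agents carry WSS near the closed form for the lumen radius
  wan <- 4 * fp$viscosity * (fp$inlet_velocity * 1e-3) /
    (vs$lumen_radius * 1e-3)
  lf <- a2$lumen_facing & inner
  expect_gt(mean(lf[inner]), 0.5)
  expect_lt(abs(median(a2$wss[lf]) / wan - 1), 0.10)
  # buried medial agents carry none
  buried <- a2$kind == "SMC" & pr$rho > vs$lumen_radius + 3 *
    vs$agent_nominal_radius
  expect_true(all(a2$wss[buried] == 0))
})
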