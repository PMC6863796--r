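test_that("zero expansion leaves the wall untouched", {
  v <- tiny_vessel()
  vs <- attr(v, "vessel_spec")
  # a small stent already at its (non-contacting) target inside the lumen
  sp <- stent_spec(n_rings = 1, struts_per_ring = 6, strut_length = 0.2,
                   target_radius = 0.08, strut_width = 0.04,
                   strut_thickness = 0.03, voxel_edge = 0.03)
  st <- generate_parametric_stent(sp, segment_length = vs$segment_length)
  dep <- deploy(v, st$agents, expand_from = 1)
  expect_length(dep$report$ruptured_iel, 0)
  expect_length(dep$report$ruptured_eel, 0)
  wall <- dep$state$agents[seq_len(nrow(v)), ]
  disp <- sqrt((wall$x - v$x)^2 + (wall$y - v$y)^2 + (wall$z - v$z)^2)
  expect_lt(max(disp), 1e-3)
})

test_that("oversized deployment: strut-focal injury, monotone expansion, rigid stent", {
  dep <- small_deployment()
  rep <- dep$report
  st <- dep$state$agents
  nw <- nrow(st) - sum(st$kind == "STENT")

  # ruptures happened and their recorded peak strain exceeds the threshold
  expect_gt(length(rep$ruptured_iel), 0)
  expect_true(all(rep$peak_strain[rep$ruptured_iel] >
                    bio_params()$iel_rupture_strain))
  # rupture sets are disjoint and refer to wall agents
  expect_length(intersect(rep$ruptured_iel, rep$ruptured_eel), 0)
  expect_true(all(rep$ruptured_iel <= nw))

  # in a straight vessel, ruptured sites sit closer to the struts than
  # the surviving IEL (injury is strut-focal)
  stent <- st[st$kind == "STENT", ]
  d_to_stent <- function(idx)
    median(stentsim:::cpp_nearest_dist(st$x[idx], st$y[idx], st$z[idx],
                                       stent$x, stent$y, stent$z))
  intact <- which(st$kind == "IEL_SMC")
  expect_lt(d_to_stent(rep$ruptured_iel), d_to_stent(intact))

  # lumen radius is non-decreasing through the expansion schedule
  # (sub-0.1 um relaxation noise allowed)
  expect_true(all(diff(rep$lumen_radius_series) > -1e-4))

  # stent agents never move (rigid boundary)
  sidx <- which(st$kind == "STENT")
  expect_true(all(!st$mobile[sidx]))

  # wall-strut contact map refers to touching pairs
  expect_gt(nrow(rep$contact), 0)
  d_contact <- sqrt((st$x[rep$contact$wall_id] - st$x[rep$contact$stent_id])^2 +
                    (st$y[rep$contact$wall_id] - st$y[rep$contact$stent_id])^2 +
                    (st$z[rep$contact$wall_id] - st$z[rep$contact$stent_id])^2)
  expect_true(all(d_contact <= mech_params()$cutoff *
                    (st$r[rep$contact$wall_id] + st$r[rep$contact$stent_id])))
})

test_that("a straight stent in a curved vessel bends the wall at the stent ends", {
  set.seed(99)
  vs <- vessel_spec(lumen_radius = 0.2, segment_length = 1.1,
                    curvature_radius = 4, agent_nominal_radius = 0.018,
                    wall_layers = data.frame(
                      kind = c("IEL_SMC", "SMC", "EEL_SMC"),
                      n = c(1L, 1L, 1L)))
  v <- build_vessel(vs)
  sp <- stent_spec(n_rings = 2, struts_per_ring = 6, strut_length = 0.28,
                   ring_spacing = 0.4, target_radius = 0.27,
                   strut_width = 0.08, strut_thickness = 0.06,
                   curvature_radius = Inf, voxel_edge = 0.03)
  st <- generate_parametric_stent(sp, segment_length = 1.1)
  dep <- suppressWarnings(deploy(v, st$agents))
  a <- dep$state$agents
  wall <- a[a$kind != "STENT", ]
  # wall-centre path: mean radial offset from the original centreline per
  # axial bin; its discrete turning measures local bending
  pr <- stentsim:::centreline_project(vs, cbind(wall$x, wall$y, wall$z))
  bins <- cut(pr$s, breaks = seq(0, 1.1, by = 0.1))
  offs <- tapply(pr$rho * cos(pr$theta), bins, mean)  # epicardial offset
  turn <- abs(diff(diff(offs)))
  # stent spans s in [0.15, 0.95]: ends near bins 2-3 and 9-10, middle 5-7
  end_turn <- max(turn[c(2, 3, 8, 9)], na.rm = TRUE)
  mid_turn <- max(turn[5:6], na.rm = TRUE)
  expect_gt(end_turn, mid_turn)
})
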