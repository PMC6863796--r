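test_that("phenotype initialisation follows lumen exposure", {
  v <- tiny_vessel()
  vs <- attr(v, "vessel_spec")

  # intact IEL everywhere: no synthetic cells
  st <- new_sim_state(v, vs)
  st <- initialize_phenotypes(st, voxel_edge = 0.03)
  expect_equal(sum(st$agents$phenotype == "synthetic", na.rm = TRUE), 0L)
  # endothelium starts fully denuded
  expect_equal(mean(st$endo$covered), 0)

  # all IEL removed: every lumen-exposed innermost SMC turns synthetic
  v2 <- v
  v2$kind[v2$kind == "IEL_SMC"] <- "SMC"
  st2 <- initialize_phenotypes(new_sim_state(v2, vs), voxel_edge = 0.03)
  syn <- !is.na(st2$agents$phenotype) & st2$agents$phenotype == "synthetic"
  expect_identical(which(syn),
                   which(st2$agents$lumen_facing & st2$agents$kind == "SMC"))
  expect_gt(sum(syn), 0)

  # a single ruptured patch: exposure is confined to the patch and covers
  # its lumen-facing interior
  v3 <- v
  patch <- v3$kind == "IEL_SMC" & v3$y > 0.12 & abs(v3$z) < 0.15
  v3$kind[patch] <- "SMC"
  st3 <- initialize_phenotypes(new_sim_state(v3, vs), voxel_edge = 0.03)
  syn3 <- which(!is.na(st3$agents$phenotype) &
                  st3$agents$phenotype == "synthetic")
  expect_gt(length(syn3), 0)
  expect_true(all(syn3 %in% which(patch)))
  expect_true(all(st3$agents$lumen_facing[syn3]))
  expect_gt(length(syn3) / sum(patch & st3$agents$lumen_facing), 0.5)
})

make_bio_state <- function(n_syn = 20, clock = 0, strain = 0) {
  v <- tiny_vessel()
  vs <- attr(v, "vessel_spec")
  st <- initialize_phenotypes(new_sim_state(v, vs), voxel_edge = 0.03)
  a <- st$agents
  idx <- head(which(a$kind == "IEL_SMC" & a$mobile), n_syn)
  a$kind[idx] <- "SMC"
  a$phenotype[idx] <- "synthetic"
  a$cycle_clock[idx] <- clock
  a$strain[idx] <- strain
  a$lumen_facing[idx] <- TRUE
  st$agents <- a
  st$syn_idx <- idx
  st
}

test_that("growth arrest requires functional endothelium and high WSS", {
  bio <- bio_params()

  # functional endothelium + WSS above threshold: permanent arrest
  st <- make_bio_state()
  st$endo$covered[] <- TRUE
  st1 <- growth_step(st, bio, site_wss = 0.5)
  a1 <- st1$agents[st$syn_idx, ]
  expect_true(all(a1$arrested))
  expect_true(all(a1$phenotype == "contractile"))

  # arrested cells stay quiescent even if WSS later drops
  st2 <- growth_step(st1, bio, site_wss = 0.1)
  expect_true(all(st2$agents[st$syn_idx, "arrested"]))
  expect_equal(sum(st2$agents$cycle_clock), 0)

  # denuded endothelium: cells keep cycling regardless of WSS
  st3 <- make_bio_state()
  st3$endo$covered[] <- FALSE
  st3 <- growth_step(st3, bio, site_wss = 0.5)
  expect_true(all(st3$agents[st3$syn_idx, "cycle_clock"] == 1))

  # covered but low WSS: cells keep cycling
  st4 <- make_bio_state()
  st4$endo$covered[] <- TRUE
  st4 <- growth_step(st4, bio, site_wss = 0.1)
  expect_true(all(st4$agents[st4$syn_idx, "cycle_clock"] == 1))

  # contact inhibition pauses the clock
  st5 <- make_bio_state()
  st5$agents$overlap[st5$syn_idx] <- 0.2
  st5 <- growth_step(st5, bio, site_wss = 0.1)
  expect_true(all(st5$agents[st5$syn_idx, "cycle_clock"] == 0))
})

test_that("division conserves volume and yields synthetic daughters", {
  bio <- bio_params()
  st <- make_bio_state(n_syn = 10, clock = bio$cycle_duration - 1)
  st$agents$r[st$syn_idx] <- st$agents$r0[st$syn_idx] *
    (1 + (bio$cycle_duration - 1) / bio$cycle_duration)^(1 / 3)
  n0 <- nrow(st$agents)
  r0 <- st$agents$r0[st$syn_idx][1]
  set.seed(2)
  st <- growth_step(st, bio, site_wss = 0.1)
  expect_equal(nrow(st$agents), n0 + 10L)
  expect_equal(st$n_divisions, 10L)
  d <- st$agents[!is.na(st$agents$phenotype) &
                   st$agents$phenotype == "synthetic", ]
  expect_true(all(d$cycle_clock == 0))
  # two daughters of radius r0 hold the mother's final volume 2*(4/3)pi r0^3
  r_final <- r0 * 2^(1 / 3)
  expect_equal(2 * r0^3, r_final^3, tolerance = 1e-12)
  expect_true(all(abs(d$r - d$r0) < 1e-12))
})

test_that("ECM production follows the strain-gated stochastic blob rule", {
  bio <- bio_params()

  # contractile cells never produce, whatever the strain
  st <- make_bio_state(n_syn = 0)
  st$agents$strain <- 0.5
  set.seed(1)
  st <- ecm_step(st, bio)
  expect_equal(st$n_emissions, 0L)

  # synthetic at 5% strain (below the 10% gate) never starts producing
  st2 <- make_bio_state(n_syn = 50, strain = 0.05)
  set.seed(1)
  st2 <- ecm_step(st2, bio)
  expect_equal(st2$n_emissions, 0L)
  expect_false(any(st2$agents$producing_ecm))

  # above the gate: producers emit with probability P per hour, blobs are
  # placed abluminally with the volume of a contractile SMC
  st3 <- make_bio_state(n_syn = 60, strain = 0.15)
  set.seed(7)
  st3 <- ecm_step(st3, bio)
  expect_true(all(st3$agents$producing_ecm[st3$syn_idx]))
  blobs <- st3$agents[st3$agents$kind == "ECM", ]
  expect_equal(nrow(blobs), st3$n_emissions)
  expect_gt(nrow(blobs), 0)
  expect_equal(unique(blobs$r), st3$agents$r0[st3$syn_idx][1])
  # abluminal placement: outward component strictly positive relative to
  # the nearest producing cells
  vs <- st3$spec
  prb <- stentsim:::centreline_project(vs, cbind(blobs$x, blobs$y, blobs$z))
  pra <- stentsim:::centreline_project(
    vs, cbind(st3$agents$x[st3$syn_idx], st3$agents$y[st3$syn_idx],
              st3$agents$z[st3$syn_idx]))
  expect_true(all(prb$rho > min(pra$rho)))

  # emission count is binomial(n producers, P)
  st4 <- make_bio_state(n_syn = 200, strain = 0.15)
  set.seed(42)
  tot <- 0
  for (k in 1:20) {
    st4 <- ecm_step(st4, bio)
    tot <- tot + st4$n_emissions
  }
  n_trials <- 200 * 20
  expect_lt(abs(tot / n_trials - bio$ecm_probability),
            4 * sqrt(0.1 * 0.9 / n_trials))
})

test_that("ECM cohort composition matches the branching bookkeeping", {
  bio <- bio_params()
  res <- simulate_ecm_cohort(20000, bio, seed = 99)
  # long-run fraction P*cycle/(P*cycle + 2) = 3/5 at defaults
  expect_equal(bio$ecm_probability * bio$cycle_duration /
                 (bio$ecm_probability * bio$cycle_duration + 2), 0.6)
  expect_lt(abs(res$ecm_fraction - 0.6), 0.01)
  expect_lt(abs(res$mean_blobs - 3), 0.1)
})

test_that("endothelium recovery is stochastic, uniform and irreversible", {
  bio0 <- bio_params(endothelium_recovery = 0)
  st <- make_bio_state(n_syn = 0)
  st <- endothelium_step(st, bio0)
  expect_equal(mean(st$endo$covered), 0)

  bio1 <- bio_params(endothelium_recovery = 1)
  st1 <- endothelium_step(st, bio1)
  expect_equal(mean(st1$endo$covered), 1)

  # mean coverage after t hours = 1 - (1-p)^t
  p <- 0.05; t_h <- 24
  bio_p <- bio_params(endothelium_recovery = p)
  set.seed(11)
  st2 <- make_bio_state(n_syn = 0)
  for (k in seq_len(t_h)) {
    cov_before <- st2$endo$covered
    st2 <- endothelium_step(st2, bio_p)
    expect_true(all(st2$endo$covered[cov_before]))  # never reverts
  }
  n_sites <- length(st2$endo$covered)
  expected <- 1 - (1 - p)^t_h
  se <- sqrt(expected * (1 - expected) / n_sites)
  expect_lt(abs(mean(st2$endo$covered) - expected), 4 * se)
})
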