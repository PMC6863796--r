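SMC_KINDS <- c("SMC", "IEL_SMC", "EEL_SMC")

#' Classify lumen-facing agents from a voxelization
#'
#' Wall voxels with a 6-connected lumen fluid neighbour define the
#' lumen surface; the agents covering them are lumen-facing.
#'
#' @param lattice a `flow_lattice` from [voxelize()].
#' @return integer vector of lumen-facing agent ids.
#' @export
lumen_surface_ids <- function(lattice) {
  surf <- lumen_surface_voxels(lattice)
  sort(unique(lattice$owner[surf]))
}

# voxel indices of wall voxels adjacent (6-conn) to lumen fluid, with a
# recorded covering agent
lumen_surface_voxels <- function(lattice) {
  dims <- lattice$dims
  fl <- array(lattice$flags, dims)
  lum <- array(lattice$lumen, dims)
  solid <- fl == 1L
  surf <- array(FALSE, dims)
  n <- dims
  surf[-1, , ] <- surf[-1, , ] | (solid[-1, , ] & lum[-n[1], , ])
  surf[-n[1], , ] <- surf[-n[1], , ] | (solid[-n[1], , ] & lum[-1, , ])
  surf[, -1, ] <- surf[, -1, ] | (solid[, -1, ] & lum[, -n[2], ])
  surf[, -n[2], ] <- surf[, -n[2], ] | (solid[, -n[2], ] & lum[, -1, ])
  surf[, , -1] <- surf[, , -1] | (solid[, , -1] & lum[, , -n[3]])
  surf[, , -n[3]] <- surf[, , -n[3]] | (solid[, , -n[3]] & lum[, , -1])
  which(as.vector(surf) & lattice$owner > 0)
}

#' Switch lumen-exposed SMCs to the synthetic phenotype
#'
#' Immediately post-stenting, plain SMCs exposed to the lumen (medial
#' cells bared by IEL rupture, or an innermost layer without lamina
#' cover) switch to the proliferative synthetic phenotype; SMCs still
#' covered by an intact lamina stay contractile. Also initialises the
#' endothelium as fully denuded over the segment.
#'
#' @param state a `sim_state` (post-deployment).
#' @param voxel_edge voxel size used for the surface classification.
#' @return the state with phenotypes and endothelium initialised.
#' @export
initialize_phenotypes <- function(state, voxel_edge = 0.03) {
  lattice <- voxelize(state$agents, state$spec, voxel_edge)
  surf <- lumen_surface_voxels(lattice)
  a <- state$agents
  a$lumen_facing <- FALSE
  a$lumen_facing[unique(lattice$owner[surf])] <- TRUE
  a$phenotype[a$kind %in% SMC_KINDS] <- "contractile"
  # A lumen-facing SMC is exposed where the lamina is actually absent:
  # either it is itself a rupture site (an IEL-covered agent converted to
  # plain SMC during deployment), or no intact IEL-covered agent lies
  # within the lamina's own mesh size (inter-agent spacing with a stretch
  # allowance - so packing interstices of an intact lamina do not count,
  # while holes torn wider than the mesh do).
  sel <- a$kind == "SMC" & a$lumen_facing
  iel <- which(a$kind == "IEL_SMC")
  if (any(sel) && length(iel)) {
    cand <- which(sel)
    r_iel <- stats::median(a$r[iel])
    cover <- 1.12 * (a$r[cand] + r_iel)
    nn <- cpp_nearest(a$x[cand], a$y[cand], a$z[cand],
                      a$x[iel], a$y[iel], a$z[iel], max(cover) * 1.5)
    covered <- nn$index > 0 & nn$dist <= cover
    sel[cand[covered & !a$lamina_ruptured[cand]]] <- FALSE
  }
  a$phenotype[sel] <- "synthetic"
  a$cycle_clock[sel] <- 0
  state$agents <- a
  state$endo <- new_endothelium(state$spec)
  state
}

# endothelium coverage map: fixed angular x axial grid of lumen sites,
# all denuded immediately post-stenting
new_endothelium <- function(spec, site_size = 0.1) {
  n_theta <- max(8L, round(2 * pi * spec$lumen_radius / site_size))
  n_z <- max(4L, round(spec$segment_length / site_size))
  structure(list(covered = matrix(FALSE, n_theta, n_z),
                 n_theta = n_theta, n_z = n_z),
            class = "endothelium")
}

#' @export
print.endothelium <- function(x, ...) {
  cat("<endothelium>", x$n_theta, "x", x$n_z, "sites,",
      sprintf("%.1f%%", 100 * mean(x$covered)), "covered\n")
  invisible(x)
}

# (theta, s) -> site indices for agent positions
endo_site <- function(state, idx = seq_len(nrow(state$agents))) {
  a <- state$agents
  pr <- centreline_project(state$spec, cbind(a$x[idx], a$y[idx], a$z[idx]))
  it <- pmin(state$endo$n_theta,
             pmax(1L, 1L + floor((pr$theta + pi) / (2 * pi) *
                                   state$endo$n_theta)))
  iz <- pmin(state$endo$n_z,
             pmax(1L, 1L + floor(pr$s / state$spec$segment_length *
                                   state$endo$n_z)))
  cbind(it, iz)
}

#' Stochastic endothelium recovery step (1 h)
#'
#' Each denuded lumen site independently becomes covered with the
#' per-hour recovery probability; coverage never reverts. Recovery is
#' uniform over the whole stented segment.
#'
#' @param state a `sim_state`.
#' @param bio [bio_params()].
#' @return the state with updated coverage.
#' @export
endothelium_step <- function(state, bio = bio_params()) {
  cov <- state$endo$covered
  den <- which(!cov)
  if (length(den) && bio$endothelium_recovery > 0)
    cov[den] <- runif(length(den)) < bio$endothelium_recovery
  state$endo$covered <- cov
  state
}

#' Hourly growth and proliferation step
#'
#' Synthetic SMCs advance their cell-cycle clock by one hour unless
#' contact inhibited (maximum pair overlap beyond the threshold) or
#' arrested. Arrest is checked per lumen site: where the endothelium is
#' functional and the local wall shear stress exceeds the threshold,
#' synthetic SMCs at that site arrest permanently (revert to the
#' contractile phenotype and stay quiescent even if WSS later falls).
#' Cells completing the cycle divide into two synthetic daughters along
#' a random, tangentially biased axis with the combined volume
#' conserved; growing cells swell as `r0 * (1 + clock/cycle)^(1/3)`.
#'
#' @param state a `sim_state` with current WSS and strain.
#' @param bio [bio_params()].
#' @param site_wss optional matrix of per-site WSS (Pa); computed from
#'   the lumen-facing agents when missing. A scalar is recycled (used
#'   to impose a uniform WSS in controlled experiments).
#' @return the state after one hour of growth.
#' @export
growth_step <- function(state, bio = bio_params(), site_wss = NULL) {
  a <- state$agents
  smc <- a$kind %in% SMC_KINDS
  syn <- smc & !is.na(a$phenotype) & a$phenotype == "synthetic" & !a$arrested
  if (!any(syn)) {
    state$agents <- a
    return(state)
  }
  sites <- endo_site(state, which(syn))
  if (is.null(site_wss)) site_wss <- site_wss_map(state)
  if (length(site_wss) == 1L)
    site_wss <- matrix(site_wss, state$endo$n_theta, state$endo$n_z)

  covered <- state$endo$covered[sites]
  wss_loc <- site_wss[sites]
  arrest <- covered & wss_loc > bio$wss_arrest_threshold
  ia <- which(syn)[arrest]
  if (length(ia)) {
    a$arrested[ia] <- TRUE
    a$phenotype[ia] <- "contractile"
    a$producing_ecm[ia] <- FALSE
    a$r[ia] <- a$r0[ia]
    a$cycle_clock[ia] <- 0
  }
  state$n_arrests <- length(ia)

  cyc <- which(syn)[!arrest]
  inhibited <- a$overlap[cyc] > bio$contact_inhibition_threshold
  adv <- cyc[!inhibited]
  a$cycle_clock[adv] <- a$cycle_clock[adv] + bio$bio_step
  a$r[adv] <- a$r0[adv] * (1 + a$cycle_clock[adv] / bio$cycle_duration)^(1 / 3)

  div <- adv[a$cycle_clock[adv] >= bio$cycle_duration]
  state$n_divisions <- length(div)
  if (length(div)) {
    pr <- centreline_project(state$spec, cbind(a$x[div], a$y[div], a$z[div]))
    u <- matrix(rnorm(3 * length(div)), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    # bias the division axis tangentially (suppress the radial component)
    rad <- rowSums(u * pr$abluminal)
    u <- u - 0.5 * rad * pr$abluminal
    u <- u / sqrt(rowSums(u^2))
    sep <- 0.5 * a$r0[div]
    d1 <- a[div, , drop = FALSE]
    d1$x <- d1$x + sep * u[, 1]; d1$y <- d1$y + sep * u[, 2]
    d1$z <- d1$z + sep * u[, 3]
    d2 <- a[div, , drop = FALSE]
    d2$x <- d2$x - sep * u[, 1]; d2$y <- d2$y - sep * u[, 2]
    d2$z <- d2$z - sep * u[, 3]
    fix_daughter <- function(d) {
      d$r <- d$r0
      d$cycle_clock <- 0
      d$phenotype <- "synthetic"
      d$kind <- "SMC"  # daughters are plain medial SMCs (no lamina cover)
      d$arrested <- FALSE
      d
    }
    d1 <- fix_daughter(d1)
    d2 <- fix_daughter(d2)
    a <- a[-div, , drop = FALSE]
    a <- rbind(a, d1, d2)
    a$id <- seq_len(nrow(a))
    class(a) <- c("agents", "data.frame")
  }
  state$agents <- a
  state
}

# per-site mean WSS of lumen-facing agents; sites with no surface agent
# inherit the segment-wide mean (conservative: keeps arrest well defined)
site_wss_map <- function(state) {
  a <- state$agents
  m <- matrix(NA_real_, state$endo$n_theta, state$endo$n_z)
  lf <- which(a$lumen_facing)
  if (!length(lf)) {
    m[] <- 0
    return(m)
  }
  sites <- endo_site(state, lf)
  key <- (sites[, 2] - 1L) * state$endo$n_theta + sites[, 1]
  agg <- tapply(a$wss[lf], key, mean)
  m[as.integer(names(agg))] <- as.numeric(agg)
  m[is.na(m)] <- mean(a$wss[lf])
  m
}

#' Hourly stochastic extracellular-matrix production step
#'
#' Synthetic SMCs that exceed the strain threshold (10\% bond strain)
#' become producers, and producer status is inherited by daughters;
#' each producer emits, with probability P per hour, one blob of loose
#' proteoglycan-rich ECM with the volume of a contractile SMC. Blobs
#' are placed abluminally (away from the lumen, along the local
#' outward ray from the centreline with a small tangential jitter),
#' mimicking the chemotactic migration of the producing cell toward
#' the lumen. Production stops when the producer reverts to the
#' contractile phenotype (growth arrest).
#'
#' @param state a `sim_state` with current strain.
#' @param bio [bio_params()].
#' @return the state, possibly with new ECM agents appended (count in
#'   `state$n_emissions`).
#' @export
ecm_step <- function(state, bio = bio_params()) {
  a <- state$agents
  syn <- a$kind %in% SMC_KINDS & !is.na(a$phenotype) &
    a$phenotype == "synthetic" & !a$arrested
  onset <- syn & !a$producing_ecm & a$strain > bio$ecm_strain_threshold
  a$producing_ecm[onset] <- TRUE
  prod <- which(syn & a$producing_ecm)
  state$n_emissions <- 0L
  if (length(prod)) {
    emit <- prod[rbinom(length(prod), 1L, bio$ecm_probability) == 1L]
    state$n_emissions <- length(emit)
    if (length(emit)) {
      pr <- centreline_project(state$spec,
                               cbind(a$x[emit], a$y[emit], a$z[emit]))
      jit <- matrix(rnorm(3 * length(emit), sd = 1), ncol = 3)
      jit <- jit - rowSums(jit * pr$abluminal) * pr$abluminal
      jn <- sqrt(rowSums(jit^2))
      jit <- jit / pmax(jn, 1e-12)
      dir <- pr$abluminal + 0.35 * jit
      dir <- dir / sqrt(rowSums(dir^2))
      r_e <- a$r0[emit]
      dist <- 0.99 * (a$r[emit] + r_e)
      blobs <- new_agents(a$x[emit] + dist * dir[, 1],
                          a$y[emit] + dist * dir[, 2],
                          a$z[emit] + dist * dir[, 3],
                          r = r_e, kind = "ECM")
      a <- rbind(a, as.data.frame(blobs)[, names(a)])
      a$id <- seq_len(nrow(a))
      class(a) <- c("agents", "data.frame")
    }
  }
  state$agents <- a
  state
}

#' Simulate a cohort of producing SMCs through one cell cycle
#'
#' Follows `n` independent producing synthetic SMCs hour by hour
#' through one full cell cycle under the stochastic blob-emission rule
#' (one Bernoulli trial per hour at probability P), then divides each
#' cell into two daughters. Summarises the loose-ECM composition of the
#' newly formed tissue: blobs have the volume of one contractile SMC,
#' so the volume fraction is `blobs / (blobs + 2 daughters)`.
#'
#' @param n number of producing cells.
#' @param bio [bio_params()].
#' @param seed optional integer seed.
#' @return list: `blobs` per-cell counts, `mean_blobs`,
#'   `ecm_fraction`, and their Monte-Carlo standard errors.
#' @export
simulate_ecm_cohort <- function(n = 10000, bio = bio_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blobs <- integer(n)
  for (h in seq_len(round(bio$cycle_duration / bio$bio_step)))
    blobs <- blobs + rbinom(n, 1L, bio$ecm_probability)
  daughters <- 2L * n
  total_blobs <- sum(blobs)
  frac <- total_blobs / (total_blobs + daughters)
  list(blobs = blobs,
       mean_blobs = mean(blobs),
       se_blobs = sd(blobs) / sqrt(n),
       ecm_fraction = frac,
       n = n)
}
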