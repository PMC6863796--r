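#' Construct a simulation state
#'
#' Bundles the agent set, endothelium coverage, simulated time and
#' provenance into the checkpointable state threaded through the
#' multiscale loop.
#'
#' @param agents agent table.
#' @param spec the host [vessel_spec()].
#' @param time_h simulated time (hours).
#' @return object of class `sim_state`.
#' @export
new_sim_state <- function(agents, spec, time_h = 0) {
  structure(list(agents = agents, spec = spec, endo = NULL,
                 time_h = time_h, inlet_flow = NULL,
                 series = NULL, provenance = list()),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state> t =", x$time_h, "h,", nrow(x$agents), "agents (",
      sum(x$agents$kind == "ECM"), "ECM,",
      sum(x$agents$kind == "STENT"), "stent )\n")
  if (!is.null(x$endo))
    cat("  endothelium coverage",
        sprintf("%.1f%%", 100 * mean(x$endo$covered)), "\n")
  invisible(x)
}

#' Run the multiscale growth loop
#'
#' Executes the hourly cycle of the coupled model: voxelize the agent
#' geometry, solve steady flow and map WSS onto lumen-facing agents,
#' apply the biological rules (endothelium recovery, growth/division
#' with arrest, stochastic ECM production), then re-equilibrate the
#' wall mechanics. The volumetric inlet flow is fixed at its initial
#' value, so WSS rises as the lumen narrows.
#'
#' The flow solution may be refreshed every `flow_interval` hours
#' (warm-started from the previous solution) instead of every hour;
#' it is also refreshed whenever any agent moved more than half a
#' voxel since the last solve. `force_flow = TRUE` re-solves every
#' hour regardless.
#'
#' @param state a `sim_state` (deployed, equilibrated, phenotypes
#'   initialised via [initialize_phenotypes()]).
#' @param days horizon in days of simulated time.
#' @param mech,bio,flow parameter objects.
#' @param voxel_edge flow lattice voxel edge (mm).
#' @param flow_interval hours between flow refreshes.
#' @param force_flow logical; re-solve the flow every hour.
#' @param wss_override if non-NULL, skip the flow solver and impose
#'   this uniform WSS (Pa) on every lumen site (controlled
#'   experiments, e.g. isolating the arrest rule).
#' @param progress print a line every simulated day.
#' @return the final state; `state$series` holds the per-hour time
#'   series (agent counts, coverage, lumen area, events).
#' @export
run_growth <- function(state, days, mech = mech_params(),
                       bio = bio_params(), flow = flow_params(),
                       voxel_edge = flow$voxel_edge, flow_interval = 1L,
                       force_flow = FALSE, wss_override = NULL,
                       progress = FALSE) {
  stopifnot(inherits(state, "sim_state"))
  if (is.null(state$endo)) stop("run initialize_phenotypes() first")
  hours <- round(days * 24)
  state$provenance$horizon_days <- days
  if (hours == 0) return(state)

  series <- vector("list", hours)
  lattice <- NULL
  last_solve_pos <- NULL
  wall_time0 <- Sys.time()

  for (hh in seq_len(hours)) {
    a <- state$agents
    if (is.null(wss_override)) {
      moved <- if (is.null(last_solve_pos) ||
                   nrow(last_solve_pos) != nrow(a)) Inf
               else max(abs(a$x - last_solve_pos$x) +
                        abs(a$y - last_solve_pos$y) +
                        abs(a$z - last_solve_pos$z))
      due <- force_flow || hh == 1L || (hh - 1L) %% flow_interval == 0L
      if (due && moved > voxel_edge / 2) {
        prev <- lattice
        # freeze the lattice box after the first voxelization so the
        # previous solution can warm-start every refresh
        lattice <- if (is.null(state$provenance$flow_box)) NULL else
          tryCatch(voxelize(a, state$spec, voxel_edge,
                            box = state$provenance$flow_box),
                   error = function(e) NULL)
        if (is.null(lattice)) { # first solve, or wall outgrew the box
          lattice <- voxelize(a, state$spec, voxel_edge)
          state$provenance$flow_box <- list(origin = lattice$origin,
                                            dims = lattice$dims)
        }
        warm <- if (!is.null(prev) && !is.null(prev$velocity) &&
                    identical(prev$dims, lattice$dims)) prev$velocity
        lattice <- solve_flow(lattice, flow, inlet_flow = state$inlet_flow,
                              warm_start = warm)
        state$inlet_flow <- lattice$inlet_flow
        state$agents <- map_wss_to_agents(lattice, a)
        last_solve_pos <- state$agents[, c("x", "y", "z")]
      } else if (!is.null(lattice)) {
        # geometry unchanged enough: keep previous WSS mapping
      }
      site_wss <- NULL
    } else {
      # imposed uniform WSS: the arrest check runs per site, so no flow
      # solve or surface classification is needed (and the trajectory
      # stays a pure function of the state)
      site_wss <- wss_override
    }

    state <- endothelium_step(state, bio)
    state <- growth_step(state, bio, site_wss = site_wss)
    state <- ecm_step(state, bio)
    state <- integrate_to_equilibrium(state, mech)
    state$time_h <- state$time_h + 1

    lum_area <- if (!is.null(lattice))
      lattice$n_lumen * voxel_edge^3 / state$spec$segment_length
    else NA_real_
    series[[hh]] <- data.frame(
      time_h = state$time_h,
      n_smc = sum(state$agents$kind %in% SMC_KINDS),
      n_ecm = sum(state$agents$kind == "ECM"),
      n_synthetic = sum(!is.na(state$agents$phenotype) &
                          state$agents$phenotype == "synthetic"),
      coverage = mean(state$endo$covered),
      lumen_area = lum_area,
      divisions = state$n_divisions %||% 0L,
      emissions = state$n_emissions %||% 0L,
      arrests = state$n_arrests %||% 0L)
    if (progress && hh %% 24 == 0)
      message(sprintf("day %d: %d agents, coverage %.0f%%, %.1fs",
                      hh %/% 24, nrow(state$agents),
                      100 * mean(state$endo$covered),
                      as.numeric(difftime(Sys.time(), wall_time0,
                                          units = "secs"))))
  }
  new_series <- do.call(rbind, series)
  state$series <- if (is.null(state$series)) new_series
                  else rbind(state$series, new_series)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

CHECKPOINT_VERSION <- 1L

#' Checkpoint a simulation state to disk
#'
#' Lossless snapshot including the R random-number-generator state, so
#' a restored run continues bit-identically.
#'
#' @param state a `sim_state`.
#' @param path output file.
#' @export
checkpoint_state <- function(state, path) {
  rng <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  saveRDS(list(version = CHECKPOINT_VERSION, state = state, rng = rng),
          path)
  invisible(path)
}

#' Restore a checkpoint written by [checkpoint_state()]
#' @param path checkpoint file.
#' @return the restored `sim_state` (the RNG state is restored too).
#' @export
restore_state <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupted checkpoint: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$version))
    stop("corrupted checkpoint: missing version")
  if (obj$version != CHECKPOINT_VERSION)
    stop("checkpoint version mismatch: file has ", obj$version,
         ", expected ", CHECKPOINT_VERSION)
  if (!is.null(obj$rng))
    assign(".Random.seed", obj$rng, envir = globalenv())
  obj$state
}
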