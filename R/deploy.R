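#' Deploy a stent into a vessel by quasi-static radial expansion
#'
#' Stent agents are first mapped radially toward the vessel centreline
#' (crimped state), then expanded linearly to their original (target)
#' positions over `n_steps` quasi-static steps, relaxing the wall to
#' mechanical equilibrium after every step; the stent itself is a rigid
#' boundary throughout. Per-agent peak bond strain is tracked across the
#' schedule; IEL-covered SMCs whose peak strain exceeds the IEL rupture
#' threshold are converted to plain SMCs (lamina rupture, weaker
#' attraction, the surrounding intact lamina retracts), and likewise for
#' the EEL at its higher threshold.
#'
#' @param vessel wall agent table from [build_vessel()] (carries its
#'   `vessel_spec` attribute).
#' @param stent STENT agent table at deployed (target) positions, e.g.
#'   from [generate_parametric_stent()] or [fill_stent_mesh()].
#' @param mech [mech_params()].
#' @param bio [bio_params()] (supplies the rupture thresholds).
#' @param n_steps expansion steps (linear radial interpolation).
#' @param expand_from initial radial scale of the crimped stent
#'   relative to target (1 = already at target, i.e. zero expansion).
#' @return list with `state` (a `sim_state`, stent merged in and wall
#'   re-equilibrated) and `report` (class `deployment_report`):
#'   per-wall-agent peak strain, ruptured IEL/EEL agent ids (ids in the
#'   merged state), strut-wall contact map, and the per-step mean
#'   inner-surface radius `lumen_radius_series`.
#' @export
deploy <- function(vessel, stent, mech = mech_params(), bio = bio_params(),
                   n_steps = 20, expand_from = 0.4) {
  vspec <- attr(vessel, "vessel_spec")
  stopifnot(!is.null(vspec), all(stent$kind == "STENT"))
  nw <- nrow(vessel)
  ns <- nrow(stent)
  stent$mobile <- FALSE

  proj <- centreline_project(vspec, cbind(stent$x, stent$y, stent$z))
  target <- cbind(stent$x, stent$y, stent$z)

  state_agents <- bind_agents(vessel, stent)
  widx <- seq_len(nw)
  sidx <- nw + seq_len(ns)
  peak <- rep(0, nw)
  inner_set <- widx[vessel$kind == "IEL_SMC"]  # initial lumen surface layer
  ruptured_iel <- integer(0)
  ruptured_eel <- integer(0)
  lumen_series <- numeric(0)
  converged <- TRUE

  fractions <- if (expand_from >= 1) 1 else seq(expand_from, 1,
                                                length.out = n_steps + 1)[-1]
  # intermediate fractions get a bounded relaxation budget; the final state
  # is equilibrated in full after the expansion is finished
  mech_mid <- mech
  mech_mid$max_steps <- min(mech$max_steps, 80L)
  for (f in fractions) {
    # radial interpolation: scale the offset from the centreline
    off <- target - proj$point
    pos <- proj$point + f * off
    state_agents$x[sidx] <- pos[, 1]
    state_agents$y[sidx] <- pos[, 2]
    state_agents$z[sidx] <- pos[, 3]
    state_agents <- integrate_to_equilibrium(state_agents, mech_mid)
    peak <- pmax(peak, state_agents$strain[widx])
    # lamina rupture is driven by stretch of the lamina itself, i.e. the
    # strain of bonds between agents covered by the same lamina
    lam_strain <- state_agents$strain_lamina[widx]
    iel_break <- widx[state_agents$kind[widx] == "IEL_SMC" &
                      lam_strain > bio$iel_rupture_strain]
    eel_break <- widx[state_agents$kind[widx] == "EEL_SMC" &
                      lam_strain > bio$eel_rupture_strain]
    if (length(iel_break)) {
      state_agents$kind[iel_break] <- "SMC"
      state_agents$lamina_ruptured[iel_break] <- TRUE
      ruptured_iel <- union(ruptured_iel, iel_break)
    }
    if (length(eel_break)) {
      state_agents$kind[eel_break] <- "SMC"
      state_agents$lamina_ruptured[eel_break] <- TRUE
      ruptured_eel <- union(ruptured_eel, eel_break)
    }
    prw <- centreline_project(vspec, cbind(state_agents$x[inner_set],
                                           state_agents$y[inner_set],
                                           state_agents$z[inner_set]))
    lumen_series <- c(lumen_series, mean(prw$rho))
  }
  # final equilibration after the expansion is finished
  state_agents <- integrate_to_equilibrium(state_agents, mech)
  converged <- attr(state_agents, "converged")
  peak <- pmax(peak, state_agents$strain[widx])
  if (!converged)
    warning("deployment equilibration did not reach the force tolerance; ",
            "residual force ", signif(attr(state_agents, "max_force"), 3))

  # contact map: wall agents within the interaction cutoff of a strut
  rng <- mech$cutoff * (max(state_agents$r[widx]) + max(stent$r))
  nn <- cpp_nearest(state_agents$x[widx], state_agents$y[widx],
                    state_agents$z[widx], state_agents$x[sidx],
                    state_agents$y[sidx], state_agents$z[sidx], rng)
  touching <- nn$dist <= mech$cutoff *
    (state_agents$r[widx] + state_agents$r[sidx[pmax(nn$index, 1)]])
  contact <- data.frame(wall_id = widx[which(nn$index > 0 & touching)],
                        stent_id = sidx[nn$index[which(nn$index > 0 &
                                                         touching)]])

  report <- structure(list(peak_strain = peak,
                           ruptured_iel = ruptured_iel,
                           ruptured_eel = ruptured_eel,
                           contact = contact,
                           lumen_radius_series = lumen_series,
                           converged = converged),
                      class = "deployment_report")
  state <- new_sim_state(state_agents, vspec)
  list(state = state, report = report)
}

#' @export
print.deployment_report <- function(x, ...) {
  cat("<deployment_report> peak strain", signif(max(x$peak_strain), 3),
      "|", length(x$ruptured_iel), "IEL ruptures,",
      length(x$ruptured_eel), "EEL ruptures,",
      nrow(x$contact), "wall-strut contacts\n")
  invisible(x)
}

#' Write a deployment report to CSV + JSON summary
#' @param report a `deployment_report`.
#' @param prefix output path prefix; writes `<prefix>_strain.csv` and
#'   `<prefix>_summary.json`.
#' @export
write_deployment_report <- function(report, prefix) {
  write.csv(data.frame(wall_id = seq_along(report$peak_strain),
                       peak_strain = report$peak_strain),
            paste0(prefix, "_strain.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_ruptured_iel = length(report$ruptured_iel),
                            ruptured_iel = report$ruptured_iel,
                            n_ruptured_eel = length(report$ruptured_eel),
                            ruptured_eel = report$ruptured_eel,
                            n_contacts = nrow(report$contact),
                            converged = report$converged),
                       paste0(prefix, "_summary.json"), auto_unbox = TRUE)
  invisible(prefix)
}
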