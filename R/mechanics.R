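#' Pairwise central force between two agents
#'
#' Reference (scalar) implementation of the sphere-spring pair law used
#' throughout the mechanics: with `d` the centre distance and
#' `s = r_a + r_b` the rest distance, the force on `a` along the centre
#' line is linear repulsion `k_rep (s - d)` for overlap, linear
#' attraction `-k_att_eff (d - s)` for separations up to half the cutoff
#' strain, then a linear ramp to zero at the cutoff. For a pair covered
#' by the same elastic lamina (both IEL-covered or both EEL-covered)
#' `k_att_eff` is `lamina_attraction_factor` times the plain attraction
#' stiffness. The C++ relaxation kernel implements the identical law;
#' this R version is the documented contract (and the cross-check in the
#' tests).
#'
#' @param a,b single-row agent tables (or lists with `x`, `y`, `z`, `r`,
#'   `kind`).
#' @param params [mech_params()].
#' @return length-3 force vector acting on `a` (the force on `b` is its
#'   negative).
#' @export
pairwise_force <- function(a, b, params = mech_params()) {
  dvec <- c(a$x - b$x, a$y - b$y, a$z - b$z)
  d <- sqrt(sum(dvec^2))
  s <- a$r + b$r
  if ((a$kind == "STENT" || b$kind == "STENT") && d >= s)
    return(c(0, 0, 0))  # stent material: contact repulsion only
  lampair <- a$kind %in% c("IEL_SMC", "EEL_SMC") && a$kind == b$kind
  mag <- pair_force_scalar(d, s, lampair, params)
  if (d < 1e-12) return(c(mag, 0, 0)) # deterministic fallback axis
  mag * dvec / d
}

# signed scalar magnitude (positive = repulsive) of the pair law
pair_force_scalar <- function(d, s, lampair, params) {
  ka <- params$k_attraction * ifelse(lampair, params$lamina_attraction_factor, 1)
  cutoff <- params$cutoff
  epk <- (cutoff - 1) / 2
  e <- (d - s) / s
  ifelse(d < s, params$k_repulsion * (s - d),
    ifelse(e >= cutoff - 1, 0,
      ifelse(e <= epk, -ka * (d - s),
        -ka * s * epk * ((cutoff - 1) - e) / ((cutoff - 1) - epk))))
}

#' Net forces and bond strains for an agent set
#'
#' Evaluates the pair law over all interacting pairs (uniform cell
#' lists) and returns per-agent net force components, the maximum and
#' minimum signed bond strain (`(d - s)/s` over neighbours within the
#' cutoff) and the maximum net force magnitude.
#'
#' @param agents agent table.
#' @param params [mech_params()].
#' @return list with `fx`, `fy`, `fz`, `strain_max`, `strain_min`,
#'   `max_force`.
#' @export
net_forces <- function(agents, params = mech_params()) {
  cpp_net_forces(agents$x, agents$y, agents$z, agents$r,
                 lamina_code(agents), params$k_repulsion,
                 params$k_attraction, params$lamina_attraction_factor,
                 params$cutoff)
}

#' Total potential energy of the agent set
#' @inheritParams net_forces
#' @return scalar potential energy (model units).
#' @export
potential_energy <- function(agents, params = mech_params()) {
  cpp_potential(agents$x, agents$y, agents$z, agents$r,
                lamina_code(agents), params$k_repulsion,
                params$k_attraction, params$lamina_attraction_factor,
                params$cutoff)
}

#' Equilibrium residual of an agent set
#'
#' Maximum net-force magnitude over the degrees of freedom that are
#' actually free: immobile agents (stent) are excluded and for
#' plane-constrained agents (clamped vessel ends) the force component
#' along the constraint normal is removed, since it is carried by the
#' boundary.
#'
#' @inheritParams net_forces
#' @return scalar maximum residual force.
#' @export
equilibrium_residual <- function(agents, params = mech_params()) {
  f <- net_forces(agents, params)
  fx <- f$fx; fy <- f$fy; fz <- f$fz
  n2 <- agents$cnx^2 + agents$cny^2 + agents$cnz^2
  has <- n2 > 1e-12
  if (any(has)) {
    fn <- (fx * agents$cnx + fy * agents$cny + fz * agents$cnz) / pmax(n2, 1)
    fx[has] <- fx[has] - fn[has] * agents$cnx[has]
    fy[has] <- fy[has] - fn[has] * agents$cny[has]
    fz[has] <- fz[has] - fn[has] * agents$cnz[has]
  }
  fm <- sqrt(fx^2 + fy^2 + fz^2)
  max(fm[agents$mobile], 0)
}

#' Relax an agent set to mechanical equilibrium
#'
#' Integrates the overdamped dynamics `dx/dt = F / drag` with a
#' classical fourth-order Runge-Kutta scheme and a variable step chosen
#' so no agent moves more than `params$max_disp` per step, until the
#' maximum net force on any mobile agent falls below `params$force_tol`
#' or the step budget is exhausted. Immobile agents (stent material,
#' clamped ends) do not move. Updates the per-agent `strain` column with
#' the maximum signed bond strain of the final configuration.
#'
#' @param agents agent table (or a `sim_state`, whose agents are used).
#' @param params [mech_params()].
#' @return the agents with updated positions and strain; attributes
#'   `converged`, `max_force`, `steps`.
#' @export
integrate_to_equilibrium <- function(agents, params = mech_params()) {
  state <- NULL
  if (inherits(agents, "sim_state")) {
    state <- agents
    agents <- state$agents
  }
  stopifnot(all(is.finite(agents$x)), all(is.finite(agents$y)),
            all(is.finite(agents$z)))
  res <- cpp_relax(agents$x, agents$y, agents$z, agents$r,
                   lamina_code(agents), agents$mobile,
                   agents$cnx, agents$cny, agents$cnz,
                   params$k_repulsion, params$k_attraction,
                   params$lamina_attraction_factor, params$cutoff,
                   params$drag, params$force_tol, params$max_disp,
                   params$max_steps)
  agents$x <- res$x
  agents$y <- res$y
  agents$z <- res$z
  agents$strain <- res$strain_max
  agents$overlap <- -res$strain_min  # max pair overlap as rest-distance fraction
  agents$strain_lamina <- res$strain_lamina
  attr(agents, "converged") <- res$converged
  attr(agents, "max_force") <- res$max_force
  attr(agents, "steps") <- res$steps
  if (!res$converged)
    attr(agents, "residual") <- res$max_force
  if (!is.null(state)) {
    state$agents <- agents
    state$mech_converged <- res$converged
    return(state)
  }
  agents
}
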