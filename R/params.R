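#' Mechanical interaction parameters
#'
#' Parameters of the sphere-spring pair law and of the overdamped
#' variable-step RK4 relaxation used to keep the wall in mechanical
#' equilibrium. The pair force is central: linear repulsion for
#' overlapping agents, linear attraction for separated agents up to half
#' the cutoff strain, then a linear ramp down to zero at the cutoff (so
#' the force is continuous and relaxation descends a potential). Pairs of
#' lamina-covered agents of the same lamina (both IEL-covered or both
#' EEL-covered) attract with `lamina_attraction_factor` times the plain
#' attraction, which lets a ruptured lamina retract and shed strain.
#'
#' @param k_repulsion repulsion stiffness (force per mm of overlap).
#' @param k_attraction attraction stiffness (force per mm of separation).
#' @param lamina_attraction_factor multiplier on attraction for
#'   same-lamina pairs; 2 by default.
#' @param cutoff attraction cutoff as a multiple of the rest distance
#'   (sum of rest radii); beyond it agents do not interact.
#' @param drag drag coefficient of the overdamped dynamics (force·time
#'   per mm); only sets the pseudo-time scale.
#' @param force_tol equilibrium tolerance on the maximum per-agent net
#'   force magnitude.
#' @param max_disp displacement cap per RK4 step (mm); the variable step
#'   size is chosen so the leading-order move never exceeds it.
#' @param max_steps RK4 step budget per relaxation call.
#' @return an object of class `mech_params`.
#' @export
mech_params <- function(k_repulsion = 1.0,
                        k_attraction = 0.3,
                        lamina_attraction_factor = 2.0,
                        cutoff = 1.3,
                        drag = 1.0,
                        force_tol = 5e-4,
                        max_disp = 0.004,
                        max_steps = 2000) {
  stopifnot(k_repulsion > 0, k_attraction > 0,
            lamina_attraction_factor > 0, cutoff > 1,
            drag > 0, force_tol > 0, max_disp > 0, max_steps >= 1)
  structure(list(k_repulsion = k_repulsion, k_attraction = k_attraction,
                 lamina_attraction_factor = lamina_attraction_factor,
                 cutoff = cutoff, drag = drag, force_tol = force_tol,
                 max_disp = max_disp, max_steps = as.integer(max_steps)),
            class = "mech_params")
}

#' Biological ruleset parameters
#'
#' Hourly rules for smooth muscle cell (SMC) proliferation, growth
#' arrest, re-endothelialisation and stochastic production of loose
#' proteoglycan-rich extracellular matrix (ECM).
#'
#' @param bio_step biological time step in hours (fixed at 1 h).
#' @param cycle_duration SMC cell-cycle duration in hours. The default
#'   30 h makes the expected blob count per producing cell per cycle
#'   equal `ecm_probability * cycle_duration` = 3, i.e. 60\% of newly
#'   formed tissue is loose ECM.
#' @param ecm_probability probability per hour that a producing SMC
#'   emits one ECM blob (P = 0.1).
#' @param ecm_strain_threshold bond strain above which a synthetic SMC
#'   starts producing ECM (0.10, i.e. 10\% mechanical strain).
#' @param wss_arrest_threshold wall shear stress (Pa) above which, in
#'   the presence of functional endothelium, a synthetic SMC arrests
#'   permanently (0.27 Pa).
#' @param endothelium_recovery per-hour probability that a denuded
#'   lumen site regains functional endothelium. The default gives
#'   ~90\% coverage by day 10 and near-complete coverage in the third
#'   week, the time scale of re-endothelialisation in healthy porcine
#'   coronaries.
#' @param contact_inhibition_threshold pair overlap (fraction of the
#'   rest distance) beyond which a cell is contact inhibited.
#' @param iel_rupture_strain peak bond strain converting an IEL-covered
#'   SMC into a plain SMC (lamina rupture). Expressed as a strain; must
#'   stay below `cutoff - 1`, where bonds detach. Calibration value, the
#'   underlying elastin rupture strain is not fixed by the growth rules.
#' @param eel_rupture_strain like `iel_rupture_strain` for the EEL;
#'   close to the bond-detachment limit so it breaks only in the most
#'   extreme cases.
#' @return an object of class `bio_params`.
#' @export
bio_params <- function(bio_step = 1,
                       cycle_duration = 30,
                       ecm_probability = 0.1,
                       ecm_strain_threshold = 0.10,
                       wss_arrest_threshold = 0.27,
                       endothelium_recovery = 0.009,
                       contact_inhibition_threshold = 0.15,
                       iel_rupture_strain = 0.20,
                       eel_rupture_strain = 0.28) {
  stopifnot(bio_step == 1, cycle_duration > 0,
            ecm_probability >= 0, ecm_probability <= 1,
            ecm_strain_threshold > 0, wss_arrest_threshold > 0,
            endothelium_recovery >= 0, endothelium_recovery <= 1,
            contact_inhibition_threshold > 0,
            iel_rupture_strain > 0, eel_rupture_strain >= iel_rupture_strain)
  structure(list(bio_step = bio_step, cycle_duration = cycle_duration,
                 ecm_probability = ecm_probability,
                 ecm_strain_threshold = ecm_strain_threshold,
                 wss_arrest_threshold = wss_arrest_threshold,
                 endothelium_recovery = endothelium_recovery,
                 contact_inhibition_threshold = contact_inhibition_threshold,
                 iel_rupture_strain = iel_rupture_strain,
                 eel_rupture_strain = eel_rupture_strain),
            class = "bio_params")
}

#' Blood flow (lattice-Boltzmann) parameters
#'
#' Steady Newtonian flow solved with a D3Q19 BGK lattice-Boltzmann
#' method; Poiseuille velocity profile at the inlet, zero-gradient
#' outlet, half-way bounce-back walls. Physical-to-lattice unit mapping
#' keeps the lattice velocity at or below `u_lattice` and the relaxation
#' time within (0.5, 2).
#'
#' @param viscosity dynamic viscosity of blood (Pa s).
#' @param density blood density (kg per cubic metre).
#' @param voxel_edge lattice voxel edge (mm).
#' @param inlet_velocity mean inlet velocity (mm per s). The default
#'   gives mid-physiological coronary wall shear stress (~1-2 Pa) in an
#'   unstented tube of millimetre-scale radius, so the 0.27 Pa arrest
#'   threshold is meaningfully exercised.
#' @param u_lattice target maximum lattice velocity (bounds
#'   compressibility error).
#' @param conv_tol relative L2 velocity change between convergence
#'   checks at which the solver stops.
#' @param max_sweeps sweep budget.
#' @param check_every sweeps between convergence checks.
#' @return an object of class `flow_params`.
#' @export
flow_params <- function(viscosity = 3.5e-3,
                        density = 1050,
                        voxel_edge = 0.03,
                        inlet_velocity = 130,
                        u_lattice = 0.08,
                        conv_tol = 1e-6,
                        max_sweeps = 20000,
                        check_every = 50) {
  stopifnot(viscosity > 0, density > 0, voxel_edge > 0,
            inlet_velocity >= 0, u_lattice > 0, u_lattice < 0.3,
            conv_tol > 0, max_sweeps >= 1)
  structure(list(viscosity = viscosity, density = density,
                 voxel_edge = voxel_edge, inlet_velocity = inlet_velocity,
                 u_lattice = u_lattice, conv_tol = conv_tol,
                 max_sweeps = as.integer(max_sweeps),
                 check_every = as.integer(check_every)),
            class = "flow_params")
}
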