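#' Parametric vessel description
#'
#' A straight cylinder or a toroidal (planar-arc) segment of coronary
#' artery wall, built from concentric shells of spherical agents. The
#' innermost shell is IEL-covered smooth muscle, the outermost is
#' EEL-covered smooth muscle, with plain medial SMC shells in between.
#'
#' @param lumen_radius lumen radius (mm).
#' @param segment_length centreline arc length (mm).
#' @param curvature_radius radius of the centreline arc (mm); `Inf` for
#'   a straight vessel. The toroidal segments use 28 mm, a mid-range
#'   curvature for the porcine right coronary artery.
#' @param agent_nominal_radius nominal agent rest radius (mm); 15 um by
#'   default (cell scale, consistent with 30 um stent voxels).
#' @param wall_layers data frame with columns `kind`, `n` describing the
#'   shells from the lumen outward. Defaults to 1 IEL-covered layer, 4
#'   medial SMC layers and 1 EEL-covered layer (porcine media thickness
#'   of roughly 100-180 um at this agent size).
#' @return object of class `vessel_spec`.
#' @export
vessel_spec <- function(lumen_radius = 1.25,
                        segment_length = 6,
                        curvature_radius = Inf,
                        agent_nominal_radius = 0.015,
                        wall_layers = default_wall_layers()) {
  stopifnot(lumen_radius > 0, segment_length > 0,
            agent_nominal_radius > 0, curvature_radius > 0)
  stopifnot(is.data.frame(wall_layers), all(c("kind", "n") %in% names(wall_layers)))
  kinds <- rep(wall_layers$kind, wall_layers$n)
  if (kinds[1] != "IEL_SMC" || kinds[length(kinds)] != "EEL_SMC")
    stop("innermost layer must be IEL_SMC and outermost EEL_SMC")
  thickness <- 2 * agent_nominal_radius * length(kinds)
  if (is.finite(curvature_radius) &&
      curvature_radius <= lumen_radius + thickness)
    stop("self-intersecting torus: curvature_radius must exceed lumen ",
         "radius plus wall thickness")
  structure(list(lumen_radius = lumen_radius,
                 segment_length = segment_length,
                 curvature_radius = curvature_radius,
                 agent_nominal_radius = agent_nominal_radius,
                 wall_layers = wall_layers,
                 layer_kinds = kinds),
            class = "vessel_spec")
}

#' @export
print.vessel_spec <- function(x, ...) {
  cat("<vessel_spec> lumen", x$lumen_radius, "mm, length",
      x$segment_length, "mm,",
      if (is.finite(x$curvature_radius))
        paste("curvature radius", x$curvature_radius, "mm")
      else "straight", "\n")
  invisible(x)
}

default_wall_layers <- function() {
  data.frame(kind = c("IEL_SMC", "SMC", "EEL_SMC"), n = c(1L, 4L, 1L),
             stringsAsFactors = FALSE)
}

# Centreline frame at arc length s in [0, L].
# Straight vessels run along +z from z = -L/2; curved centrelines are a
# planar circular arc in the x-z plane with the curvature centre at
# (R_curv, 0, 0), so the outer (epicardial) curve points toward -x.
centreline_frame <- function(spec, s) {
  L <- spec$segment_length
  if (!is.finite(spec$curvature_radius)) {
    n <- length(s)
    return(list(point = cbind(0, 0, s - L / 2),
                tangent = cbind(rep(0, n), 0, 1),
                outward = cbind(rep(-1, n), 0, 0),
                binormal = cbind(rep(0, n), 1, 0)))
  }
  Rc <- spec$curvature_radius
  phi <- (s - L / 2) / Rc
  list(point = cbind(Rc * (1 - cos(phi)), 0, Rc * sin(phi)),
       tangent = cbind(sin(phi), 0, cos(phi)),
       outward = cbind(-cos(phi), 0, sin(phi)),
       binormal = cbind(0, rep(1, length(s)), 0))
}

# For points (n x 3): nearest centreline point, abluminal unit vector,
# arc position s and cross-section polar angle theta (0 = epicardial).
centreline_project <- function(spec, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  L <- spec$segment_length
  if (!is.finite(spec$curvature_radius)) {
    cl <- cbind(0, 0, pts[, 3])
    d <- pts - cl
    rho <- sqrt(d[, 1]^2 + d[, 2]^2)
    ab <- cbind(ifelse(rho > 0, d[, 1] / rho, 1),
                ifelse(rho > 0, d[, 2] / rho, 0), 0)
    theta <- atan2(d[, 2], -d[, 1])
    return(list(point = cl, abluminal = ab, s = pts[, 3] + L / 2,
                rho = rho, theta = theta))
  }
  Rc <- spec$curvature_radius
  qx <- pts[, 1] - Rc
  qz <- pts[, 3]
  dax <- sqrt(qx^2 + qz^2)
  ux <- qx / dax
  uz <- qz / dax
  cl <- cbind(Rc + Rc * ux, pts[, 2] * 0, Rc * uz)
  d <- pts - cl
  rho <- sqrt(rowSums(d^2))
  ab <- d / pmax(rho, 1e-12)
  phi <- atan2(qz, -qx)
  # theta from the outward (epicardial) direction U = (-cos phi, 0, sin phi)
  outc <- d[, 1] * (-cos(phi)) + d[, 3] * sin(phi)
  theta <- atan2(d[, 2], outc)
  list(point = cl, abluminal = ab, s = phi * Rc + L / 2, rho = rho,
       theta = theta)
}

#' Local toroidal metric factor
#'
#' Ratio between the local circumference of the torus at a wall point
#' and the centreline circumference: `(R_curv + h) / R_curv` where `h`
#' is the signed distance from the centreline surface toward the outer
#' curve. Rest radii of wall agents are scaled by this factor so that a
#' curved vessel is built without axial strain. Identically 1 for
#' straight vessels.
#'
#' @param position point or n-by-3 matrix of points (mm).
#' @param spec a [vessel_spec()].
#' @return numeric vector of dimensionless factors.
#' @export
local_metric_factor <- function(position, spec) {
  pts <- matrix(as.numeric(position), ncol = 3)
  if (!is.finite(spec$curvature_radius)) return(rep(1, nrow(pts)))
  Rc <- spec$curvature_radius
  sqrt((pts[, 1] - Rc)^2 + pts[, 3]^2) / Rc
}

#' Build a vessel wall in mechanical equilibrium
#'
#' Places agents on concentric shells around the (straight or toroidal)
#' centreline: rings of equal angular spacing, axial rows staggered by
#' half a spacing (hexagonal-like packing), one shell per wall layer.
#' For curved vessels each agent's rest radius is the nominal radius
#' times the local metric factor, which removes the systematic axial
#' misfit of a bent packing; the residual (sub-percent) circumferential
#' incommensurability between shells is then taken out by a short
#' in-build equilibration, so the returned wall satisfies
#' `max |net force| < mech$force_tol` as built. The first and last
#' axial rows are pinned (clamped vessel ends).
#'
#' @param spec a [vessel_spec()].
#' @param seed integer seed (reserved for reproducibility of any
#'   stochastic placement; the default packing is deterministic).
#' @param mech [mech_params()] used for the in-build equilibration.
#' @param equilibrate logical; set FALSE to return the raw packing.
#' @return agent table with attributes `vessel_spec`, `residual_force`
#'   (max net force before equilibration) and `converged`.
#' @export
build_vessel <- function(spec, seed = 1L, mech = mech_params(),
                         equilibrate = TRUE) {
  stopifnot(inherits(spec, "vessel_spec"))
  r0 <- spec$agent_nominal_radius
  kinds <- spec$layer_kinds
  nl <- length(kinds)
  L <- spec$segment_length
  ds <- 2 * r0 * sqrt(3) / 2
  nrow_ax <- max(3L, floor(L / ds) + 1L)
  svals <- seq(0, L, length.out = nrow_ax)
  frames <- centreline_frame(spec, svals)

  # Cross-section ring geometry. For curved vessels the local metric factor
  # f = 1 + (rho/R_curv) cos(theta) scales rest radii; rings are laid out so
  # that circumferential arc gaps, radial layer gaps and axial row gaps all
  # match the scaled rest distances to first order in rho/R_curv.
  curv <- is.finite(spec$curvature_radius)
  Rc <- spec$curvature_radius
  mgrid <- seq(0, 2 * pi, length.out = 1441L)
  ffac <- function(rho, th) if (curv) 1 + rho * cos(th) / Rc else
    rep(1, length(th))
  # march layer radii outward per grid angle
  rho_l <- matrix(0, nl, length(mgrid))
  rho_prev <- rep(spec$lumen_radius, length(mgrid))
  for (l in seq_len(nl)) {
    rme <- rho_prev + r0 * ffac(rho_prev + r0, mgrid)
    rho_l[l, ] <- rme
    rho_prev <- rme + r0 * ffac(rme + r0, mgrid)
  }

  acc <- vector("list", nl * nrow_ax)
  k_acc <- 0L
  for (l in seq_len(nl)) {
    rho_th <- rho_l[l, ]
    # cumulative bond coordinate: d(bond)/d(theta) = rho / (2 r0 f)
    integ <- rho_th / (2 * r0 * ffac(rho_th, mgrid))
    B <- c(0, cumsum((integ[-1] + integ[-length(integ)]) / 2 *
                       diff(mgrid)))
    ntheta <- max(6L, floor(B[length(B)]))  # gaps, never overlaps
    off_l <- 0.37 * l
    for (j in seq_len(nrow_ax)) {
      tau <- ((seq_len(ntheta) - 1) + 0.5 * (j %% 2) + off_l) %%
        ntheta / ntheta * B[length(B)]
      th <- approx(B, mgrid, xout = tau, rule = 2)$y
      rho <- approx(mgrid, rho_th, xout = th, rule = 2)$y
      px <- frames$point[j, 1] + rho * (cos(th) * frames$outward[j, 1] +
                                        sin(th) * frames$binormal[j, 1])
      py <- frames$point[j, 2] + rho * (cos(th) * frames$outward[j, 2] +
                                        sin(th) * frames$binormal[j, 2])
      pz <- frames$point[j, 3] + rho * (cos(th) * frames$outward[j, 3] +
                                        sin(th) * frames$binormal[j, 3])
      tn <- if (j == 1 || j == nrow_ax) frames$tangent[j, ] else c(0, 0, 0)
      k_acc <- k_acc + 1L
      acc[[k_acc]] <- list(x = px, y = py, z = pz,
                           kind = rep(kinds[l], ntheta),
                           cn = matrix(tn, ntheta, 3, byrow = TRUE))
    }
  }
  xs <- unlist(lapply(acc, `[[`, "x"))
  ys <- unlist(lapply(acc, `[[`, "y"))
  zs <- unlist(lapply(acc, `[[`, "z"))
  kk <- unlist(lapply(acc, `[[`, "kind"))
  cn <- do.call(rbind, lapply(acc, `[[`, "cn"))
  rs <- spec$agent_nominal_radius * local_metric_factor(cbind(xs, ys, zs), spec)
  ag <- new_agents(xs, ys, zs, rs, kind = kk, phenotype = "contractile")
  ag$cnx <- cn[, 1]; ag$cny <- cn[, 2]; ag$cnz <- cn[, 3]
  resid0 <- equilibrium_residual(ag, mech)
  conv <- TRUE
  if (equilibrate) {
    ag <- integrate_to_equilibrium(ag, mech)
    conv <- attr(ag, "converged")
  }
  attr(ag, "vessel_spec") <- spec
  attr(ag, "residual_force") <- resid0
  attr(ag, "converged") <- conv
  ag
}
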