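#' Voxelize an agent geometry for the flow solver
#'
#' Maps agents onto a regular voxel grid: voxels whose centre lies
#' inside any agent sphere become wall, the remainder is classified by
#' flood fill from the vessel centreline into lumen (fluid) and
#' exterior (treated as solid). Lumen cells on the first and last axial
#' slices are flagged inlet and outlet. Each wall voxel records the
#' covering agent with the nearest centre, which is how wall shear
#' stress is later mapped back to agents.
#'
#' For voxels coarser than the agents, spheres are rasterised with an
#' effective radius of at least 0.62 voxel edges so that a contiguous
#' agent layer cannot leak between voxel centres.
#'
#' @param agents agent table.
#' @param spec the [vessel_spec()] (provides centreline seeds and ends).
#' @param voxel_edge voxel edge (mm).
#' @param pad lateral padding in voxels around the agent extent.
#' @param entrance length (mm) of an analytic entrance tube prepended
#'   upstream along the centreline (radius = the unstented lumen
#'   radius). Used to let curved-vessel flow develop before the
#'   segment of interest, as is standard for bent-tube haemodynamics.
#' @param box optional list(origin, dims) freezing the lattice box
#'   (e.g. to keep dimensions stable across repeated solves so the
#'   previous solution can warm-start the next).
#' @return object of class `flow_lattice`: flags (0 fluid, 1 solid,
#'   2 inlet, 3 outlet), owner map, dims, origin, voxel edge.
#' @export
voxelize <- function(agents, spec, voxel_edge = 0.03, pad = 2L,
                     entrance = 0, box = NULL) {
  h <- voxel_edge
  r_eff <- pmax(agents$r, 0.62 * h)
  if (is.null(box)) {
    # clip the axial extent inside the open tube ends so that every z-plane
    # of the domain cuts a closed wall annulus (curved segments have tilted
    # end faces, so the margin includes the tilt extent)
    margin <- 2 * h
    if (is.finite(spec$curvature_radius)) {
      pr <- centreline_project(spec, cbind(agents$x, agents$y, agents$z))
      margin <- margin + max(pr$rho) *
        sin(spec$segment_length / (2 * spec$curvature_radius))
    }
    lo <- c(min(agents$x - r_eff), min(agents$y - r_eff),
            min(agents$z) + margin)
    hi <- c(max(agents$x + r_eff), max(agents$y + r_eff),
            max(agents$z) - margin)
    lo[1:2] <- lo[1:2] - pad * h
    hi[1:2] <- hi[1:2] + pad * h
    lo[3] <- lo[3] - entrance
    if (entrance > 0 && is.finite(spec$curvature_radius)) {
      # the upstream arc drifts toward +x and its oblique end face widens
      # the footprint by 1/cos(tilt); grow the box to contain both
      Rc <- spec$curvature_radius
      phi_max <- asin(min(1, abs(lo[3]) / Rc))
      hi[1] <- max(hi[1], Rc * (1 - cos(phi_max)) +
                     spec$lumen_radius / max(cos(phi_max), 0.5) + pad * h)
    }
    dims <- pmax(3L, as.integer(ceiling((hi - lo) / h)))
  } else {
    lo <- box$origin
    dims <- box$dims
  }
  n_ent <- if (entrance > 0) as.integer(round(entrance / h)) else 0L
  vox <- cpp_voxelize(agents$x, agents$y, agents$z, r_eff,
                      lo[1], lo[2], lo[3], h, dims[1], dims[2], dims[3])
  flags <- vox$flags

  # morphological closing of the wall mask: stretched tissue can open
  # sub-voxel gaps between agent spheres; closing with a one-voxel
  # structuring element seals them without moving the wall surface
  wall <- array(flags == 1L, dims)
  closed <- close_mask(wall)
  flags <- as.integer(as.vector(closed))

  if (n_ent > 0) {
    # analytic entrance: solid except a tube of the unstented lumen
    # radius following the (extrapolated) centreline
    fl3 <- array(flags, dims)
    cx <- lo[1] + (seq_len(dims[1]) - 0.5) * h
    cy <- lo[2] + (seq_len(dims[2]) - 0.5) * h
    for (iz in seq_len(n_ent)) {
      z <- lo[3] + (iz - 0.5) * h
      if (is.finite(spec$curvature_radius)) {
        Rc <- spec$curvature_radius
        dax <- sqrt((cx - Rc)^2 + z^2)
        d2 <- outer((dax - Rc)^2, cy^2, "+")
      } else {
        d2 <- outer(cx^2, cy^2, "+")
      }
      fl3[, , iz] <- ifelse(d2 < spec$lumen_radius^2, 0L, 1L)
    }
    flags <- as.integer(as.vector(fl3))
  }

  # seeds along the centreline
  svals <- seq(0.1, 0.9, length.out = 9) * spec$segment_length
  fr <- centreline_frame(spec, svals)
  six <- floor((fr$point[, 1] - lo[1]) / h)
  siy <- floor((fr$point[, 2] - lo[2]) / h)
  siz <- floor((fr$point[, 3] - lo[3]) / h)
  ok <- six >= 0 & siy >= 0 & siz >= 0 & six < dims[1] & siy < dims[2] &
    siz < dims[3]
  seeds <- as.integer((siz[ok] * dims[2] + siy[ok]) * dims[1] + six[ok])
  lumen <- cpp_flood(flags, dims[1], dims[2], dims[3], seeds)

  # leak check: the lumen must not reach the lateral box faces
  arr <- array(lumen, dims)
  if (any(arr[1, , ]) || any(arr[dims[1], , ]) ||
      any(arr[, 1, ]) || any(arr[, dims[2], ])) {
    leak <- which(arr, arr.ind = TRUE)
    leak <- leak[leak[, 1] %in% c(1, dims[1]) | leak[, 2] %in% c(1, dims[2]), ,
                 drop = FALSE]
    stop("leaky wall: lumen reaches the lateral boundary near voxel (",
         paste(leak[1, ], collapse = ","), ")")
  }

  flags[!lumen & flags == 0L] <- 1L      # exterior is solid for the solver
  fl3 <- array(flags, dims)
  lum3 <- array(lumen, dims)
  inlet <- lum3[, , 1]
  outlet <- lum3[, , dims[3]]
  fl3[, , 1][inlet] <- 2L
  fl3[, , dims[3]][outlet] <- 3L

  # sub-voxel wall distances for the interpolated bounce-back
  qlink <- cpp_link_fractions(agents$x, agents$y, agents$z, r_eff,
                              lo[1], lo[2], lo[3], h,
                              dims[1], dims[2], dims[3], as.integer(fl3))

  structure(list(flags = as.integer(fl3), owner = vox$owner,
                 dims = dims, origin = lo, voxel_edge = h,
                 lumen = lumen, n_lumen = sum(lumen), qlink = qlink,
                 velocity = NULL, wss = NULL),
            class = "flow_lattice")
}

# one-voxel 26-neighbourhood morphological closing
close_mask <- function(m) {
  shift_or <- function(a, agg) {
    out <- a
    d <- dim(a)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
      sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
      sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
      sub <- a[sx - dx, sy - dy, sz - dz]
      if (agg == "or") out[sx, sy, sz] <- out[sx, sy, sz] | sub
      else out[sx, sy, sz] <- out[sx, sy, sz] & sub
    }
    out
  }
  dil <- shift_or(m, "or")
  # erosion treats out-of-domain as solid, so the domain boundary is kept
  ero <- dil
  d <- dim(m)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- array(TRUE, d)
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    shifted[sx, sy, sz] <- dil[sx - dx, sy - dy, sz - dz]
    ero <- ero & shifted
  }
  ero | m
}

#' @export
print.flow_lattice <- function(x, ...) {
  cat("<flow_lattice>", paste(x$dims, collapse = " x "), "voxels,",
      x$n_lumen, "lumen cells, voxel", x$voxel_edge * 1000, "um",
      if (!is.null(x$wss)) "(solved)" else "(unsolved)", "\n")
  invisible(x)
}

#' Analytic rigid-tube lattice (flow oracle geometry)
#'
#' A straight circular tube of given radius and length, voxelized
#' directly (no agents), with inlet/outlet at the axial ends. Used for
#' validating the solver against the Poiseuille closed form.
#'
#' @param radius tube radius (mm).
#' @param length tube length (mm).
#' @param voxel_edge voxel edge (mm).
#' @return a `flow_lattice`.
#' @export
tube_lattice <- function(radius, length, voxel_edge = 0.03) {
  h <- voxel_edge
  nr <- ceiling(radius / h) + 2L
  dims <- c(2L * nr + 1L, 2L * nr + 1L, as.integer(ceiling(length / h)))
  lo <- c(-(dims[1] / 2) * h, -(dims[2] / 2) * h, 0)
  cx <- lo[1] + (seq_len(dims[1]) - 0.5) * h
  cy <- lo[2] + (seq_len(dims[2]) - 0.5) * h
  rad2 <- outer(cx^2, cy^2, "+")
  solid2d <- rad2 >= radius^2
  fl3 <- array(rep(as.integer(solid2d), dims[3]), dims)
  lum3 <- fl3 == 0L
  fl3[, , 1][lum3[, , 1]] <- 2L
  fl3[, , dims[3]][lum3[, , dims[3]]] <- 3L

  # analytic sub-voxel wall fractions along each in-plane link direction
  ex <- c(0, 1, -1, 0, 0, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1, 0, 0, 0, 0)
  ey <- c(0, 0, 0, 1, -1, 0, 0, 1, -1, -1, 1, 0, 0, 0, 0, 1, -1, 1, -1)
  fluid2d <- which(!solid2d, arr.ind = TRUE)
  qx <- cx[fluid2d[, 1]]
  qy <- cy[fluid2d[, 2]]
  q2d <- matrix(0, nrow(fluid2d), 19)
  for (i in 2:19) {
    if (ex[i] == 0 && ey[i] == 0) next
    jx <- fluid2d[, 1] + ex[i]
    jy <- fluid2d[, 2] + ey[i]
    inb <- jx >= 1 & jx <= dims[1] & jy >= 1 & jy <= dims[2]
    nb_solid <- rep(FALSE, nrow(fluid2d))
    nb_solid[inb] <- solid2d[cbind(jx[inb], jy[inb])]
    sel <- which(nb_solid)
    if (!length(sel)) next
    a <- (ex[i]^2 + ey[i]^2) * h^2
    b <- 2 * (qx[sel] * ex[i] + qy[sel] * ey[i]) * h
    c0 <- qx[sel]^2 + qy[sel]^2 - radius^2
    disc <- pmax(b^2 - 4 * a * c0, 0)
    t1 <- (-b + sqrt(disc)) / (2 * a)
    q2d[sel, i] <- pmin(pmax(t1, 0.01), 1)
  }
  qlink <- numeric(prod(dims) * 19)
  cell2d <- (fluid2d[, 2] - 1L) * dims[1] + (fluid2d[, 1] - 1L)
  for (iz in seq_len(dims[3])) {
    base <- ((iz - 1L) * dims[1] * dims[2] + cell2d) * 19L
    for (i in 2:19) {
      nzq <- q2d[, i] > 0
      if (any(nzq)) qlink[base[nzq] + i] <- q2d[nzq, i]
    }
  }
  structure(list(flags = as.integer(fl3), owner = integer(prod(dims)),
                 dims = dims, origin = lo, voxel_edge = h,
                 lumen = as.vector(lum3), n_lumen = sum(lum3),
                 qlink = qlink, velocity = NULL, wss = NULL),
            class = "flow_lattice")
}

#' Solve steady flow on a lattice and compute wall shear stress
#'
#' D3Q19 BGK lattice-Boltzmann solution with half-way bounce-back
#' walls, a parabolic (Poiseuille) velocity profile imposed at the
#' inlet and a zero-gradient outlet, iterated to a steady state
#' (relative L2 velocity change below `params$conv_tol`). The
#' physical-to-lattice mapping picks the time step so the peak lattice
#' velocity is about `params$u_lattice` while keeping the BGK
#' relaxation time within (0.5, 2). WSS is evaluated at wall-adjacent
#' fluid voxels from the non-equilibrium stress tensor (the local
#' velocity-gradient tensor), extrapolated half a spacing to the wall.
#'
#' @param lattice a `flow_lattice` from [voxelize()] or
#'   [tube_lattice()].
#' @param params [flow_params()].
#' @param inlet_flow volumetric inlet flow (mm^3 per s); overrides
#'   `params$inlet_velocity` when given (used to keep the flow rate
#'   fixed while the lumen narrows).
#' @param warm_start optional velocity field list (`ux`, `uy`, `uz` in
#'   mm/s, full grid) from a previous solution.
#' @return the lattice with `velocity` (mm/s), `wss` (Pa, per voxel at
#'   wall-adjacent fluid cells), `inlet_flow` (mm^3/s), and solver
#'   diagnostics `converged`, `sweeps`, `tau`.
#' @export
solve_flow <- function(lattice, params = flow_params(), inlet_flow = NULL,
                       warm_start = NULL) {
  dims <- lattice$dims
  h <- lattice$voxel_edge
  fl3 <- array(lattice$flags, dims)
  inlet_idx <- which(fl3[, , 1] == 2L)
  if (!length(inlet_idx)) stop("lattice has no inlet cells")
  A_in <- length(inlet_idx) * h^2
  if (is.null(inlet_flow)) inlet_flow <- params$inlet_velocity * A_in
  U_mean <- inlet_flow / A_in                     # mm/s
  if (U_mean <= 0) {
    zero <- rep(0, prod(dims))
    lattice$velocity <- list(ux = zero, uy = zero, uz = zero)
    lattice$wss <- zero
    lattice$inlet_flow <- 0
    lattice$converged <- TRUE
    lattice$sweeps <- 0L
    lattice$tau <- NA_real_
    return(lattice)
  }

  # Poiseuille profile over the inlet cross-section
  ix <- (inlet_idx - 1) %% dims[1] + 1
  iy <- (inlet_idx - 1) %/% dims[1] + 1
  px <- lattice$origin[1] + (ix - 0.5) * h
  py <- lattice$origin[2] + (iy - 0.5) * h
  cxm <- mean(px); cym <- mean(py)
  R_eff <- sqrt(A_in / pi)
  d2 <- ((px - cxm)^2 + (py - cym)^2) / R_eff^2
  prof <- 2 * U_mean * pmax(0, 1 - d2)            # mm/s
  prof <- prof * U_mean / mean(prof)              # renormalise exact flux

  # unit mapping (SI internally); retried with a smaller lattice velocity
  # if the run turns out compressibility-limited (e.g. a strong
  # constriction accelerates the flow well beyond the inlet peak)
  dx <- h * 1e-3                                  # m
  nu <- params$viscosity / params$density         # m^2/s
  attempt <- function(u_lat) {
    U_max <- max(prof) * 1e-3                     # m/s
    dt <- u_lat * dx / U_max
    tau <- 3 * nu * dt / dx^2 + 0.5
    if (tau > 1.9) {
      dt <- (1.9 - 0.5) * dx^2 / (3 * nu)
      tau <- 1.9
    }
    if (tau < 0.51) {
      dt <- (0.51 - 0.5) * dx^2 / (3 * nu)
      tau <- 0.51
    }
    u_scale <- dt / dx * 1e-3                     # mm/s -> lattice
    if (max(prof) * u_scale > 0.3)
      stop("lattice Mach number too high: peak lattice velocity ",
           signif(max(prof) * u_scale, 3), " at tau = ", signif(tau, 3),
           "; refine the voxel size or reduce the inlet flow")

    uz_in <- rep(0, prod(dims))
    uz_in[inlet_idx] <- prof * u_scale
    zeros <- rep(0, prod(dims))
    if (!is.null(warm_start)) {
      ux0 <- warm_start$ux * u_scale
      uy0 <- warm_start$uy * u_scale
      uz0 <- warm_start$uz * u_scale
    } else {
      # initial guess: the inlet parabola replicated down the length
      ux0 <- zeros; uy0 <- zeros
      gx <- lattice$origin[1] + (seq_len(dims[1]) - 0.5) * h
      gy <- lattice$origin[2] + (seq_len(dims[2]) - 0.5) * h
      d2g <- (outer(gx - cxm, rep(1, dims[2])))^2 +
        (outer(rep(1, dims[1]), gy - cym))^2
      prof2d <- 2 * U_mean * pmax(0, 1 - d2g / R_eff^2) * u_scale
      uz0 <- as.vector(array(rep(prof2d, dims[3]), dims))
      uz0[lattice$flags == 1L] <- 0
    }
    res <- cpp_lbm_solve(lattice$flags, dims[1], dims[2], dims[3], tau,
                         uz_in, params$conv_tol, params$max_sweeps,
                         params$check_every, ux0, uy0, uz0,
                         lattice$qlink %||% numeric(0))
    res$tau <- tau
    res$u_scale <- u_scale
    res
  }
  u_lat <- params$u_lattice
  res <- attempt(u_lat)
  tries <- 0L
  while ((res$diverged || res$rho_drift > 0.01) && tries < 2L) {
    u_lat <- u_lat / 2
    tries <- tries + 1L
    res <- attempt(u_lat)
  }
  if (res$diverged || res$rho_drift > 0.01)
    stop("flow solver diverged: max lattice velocity ", signif(res$max_u, 3),
         ", density drift ", signif(res$rho_drift, 3), ", tau ",
         signif(res$tau, 3))
  tau <- res$tau
  u_scale <- res$u_scale

  stress_scale <- params$density / (u_scale * 1e3)^2  # lattice stress -> Pa
  lattice$velocity <- list(ux = res$ux / u_scale, uy = res$uy / u_scale,
                           uz = res$uz / u_scale)
  lattice$wss <- res$wss * stress_scale
  lattice$inlet_flow <- inlet_flow
  lattice$converged <- res$converged
  lattice$sweeps <- res$sweeps
  lattice$tau <- tau
  lattice
}

#' Map lattice wall shear stress back to lumen-facing agents
#'
#' Every wall voxel adjacent (6-connectivity) to a lumen fluid voxel
#' takes the mean WSS of its adjacent wall-boundary fluid cells; each
#' agent then receives the mean over the wall-surface voxels it covers.
#' Agents with no surface voxel get WSS 0 and are flagged as not
#' lumen-facing.
#'
#' @param lattice solved `flow_lattice`.
#' @param agents agent table the lattice was voxelized from.
#' @return agents with updated `wss` and `lumen_facing` columns.
#' @export
map_wss_to_agents <- function(lattice, agents) {
  stopifnot(!is.null(lattice$wss))
  dims <- lattice$dims
  fl <- array(lattice$flags, dims)
  w <- array(lattice$wss, dims)
  solid <- fl == 1L
  fluid <- fl == 0L | fl == 2L | fl == 3L

  shift <- function(a, d, fill = FALSE) {
    out <- array(fill, dim(a))
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    sx <- max(1, 1 + d[1]):min(nx, nx + d[1])
    sy <- max(1, 1 + d[2]):min(ny, ny + d[2])
    sz <- max(1, 1 + d[3]):min(nz, nz + d[3])
    out[sx, sy, sz] <- a[sx - d[1], sy - d[2], sz - d[3]]
    out
  }
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  acc <- array(0, dims)
  cnt <- array(0, dims)
  for (k in seq_len(6)) {
    nb_w <- shift(w, dirs[k, ])
    nb_fl <- shift(fluid & w > 0, dirs[k, ])
    add <- solid & nb_fl
    acc[add] <- acc[add] + nb_w[add]
    cnt[add] <- cnt[add] + 1
  }
  surf <- which(cnt > 0)
  voxel_wss <- acc[surf] / cnt[surf]
  owner <- lattice$owner[surf]
  keep <- owner > 0
  agg <- tapply(voxel_wss[keep], owner[keep], mean)
  agents$wss <- 0
  agents$lumen_facing <- FALSE
  ids <- as.integer(names(agg))
  agents$wss[ids] <- as.numeric(agg)
  agents$lumen_facing[ids] <- TRUE
  agents
}
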