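#' Parametric stent description
#'
#' A multi-ring slotted-tube style stent: each ring is a set of short
#' axial strut bars equally spaced around the circumference (alternate
#' rings offset by half a spacing), optionally joined by thin axial
#' connectors. Cross-sections through a ring mid-plane therefore meet
#' `struts_per_ring` strut profiles (fewer than 10, as in histology
#' landmarking practice).
#'
#' @param n_rings number of rings.
#' @param struts_per_ring strut bars per ring.
#' @param strut_width circumferential bar width (mm).
#' @param strut_thickness radial bar thickness (mm).
#' @param strut_length axial bar length (mm).
#' @param ring_spacing centre-to-centre ring spacing along the
#'   centreline (mm).
#' @param connectors `"none"` or `"alternating"` (one thin connector
#'   bar between consecutive rings).
#' @param target_radius deployed (expanded) stent radius (mm): scalar
#'   or one value per ring. Must exceed the vessel lumen radius
#'   (oversized deployment; balloon-to-artery ratios around 1.4:1 are
#'   used to induce restenosis).
#' @param curvature_radius centreline curvature radius of the deployed
#'   stent (mm), `Inf` for a straight stent. A stent straighter than
#'   the vessel reproduces the uneven inner/outer-curve injury.
#' @param voxel_edge edge of the cubic volume each stent agent
#'   represents (mm); 30 um by default.
#' @return object of class `stent_spec`.
#' @export
stent_spec <- function(n_rings = 4, struts_per_ring = 6,
                       strut_width = 0.12, strut_thickness = 0.09,
                       strut_length = 0.8, ring_spacing = 1.2,
                       connectors = "none",
                       target_radius = 1.6,
                       curvature_radius = Inf,
                       voxel_edge = 0.03) {
  stopifnot(n_rings >= 1, struts_per_ring >= 3, strut_width > 0,
            strut_thickness > 0, strut_length > 0, ring_spacing > 0,
            voxel_edge > 0, all(target_radius > 0))
  connectors <- match.arg(connectors, c("none", "alternating"))
  target_radius <- rep_len(target_radius, n_rings)
  if (any(struts_per_ring * strut_width >= 2 * pi * target_radius))
    stop("struts overlap circumferentially at the target radius")
  structure(list(n_rings = as.integer(n_rings),
                 struts_per_ring = as.integer(struts_per_ring),
                 strut_width = strut_width,
                 strut_thickness = strut_thickness,
                 strut_length = strut_length,
                 ring_spacing = ring_spacing,
                 connectors = connectors,
                 target_radius = target_radius,
                 curvature_radius = curvature_radius,
                 voxel_edge = voxel_edge),
            class = "stent_spec")
}

#' @export
print.stent_spec <- function(x, ...) {
  cat("<stent_spec>", x$n_rings, "rings x", x$struts_per_ring,
      "struts, target radius", paste(unique(x$target_radius), collapse = "/"),
      "mm\n")
  invisible(x)
}

# pseudo vessel_spec carrying the stent's own centreline geometry
stent_centreline <- function(spec, segment_length) {
  structure(list(lumen_radius = min(spec$target_radius),
                 segment_length = segment_length,
                 curvature_radius = spec$curvature_radius,
                 agent_nominal_radius = spec$voxel_edge / 2),
            class = "vessel_spec")
}

#' Generate a parametric stent (surface mesh + agents)
#'
#' Builds the deployed-shape stent along its own centreline (straight
#' or an arc of `spec$curvature_radius`), centred on the arc of a
#' vessel segment of length `segment_length`. Returns a triangulated
#' surface (one box per bar, bent to the centreline) together with the
#' agent filling of that surface at the spec's voxel pitch.
#'
#' @param spec a [stent_spec()].
#' @param segment_length length of the host vessel segment (mm); the
#'   stent is centred on it.
#' @return list with `mesh` (list of `vertices`, `faces`), `agents`
#'   (STENT agents at the deployed positions, immobile) and `spec`.
#' @export
generate_parametric_stent <- function(spec, segment_length = 6) {
  stopifnot(inherits(spec, "stent_spec"))
  cl <- stent_centreline(spec, segment_length)
  stent_len <- (spec$n_rings - 1) * spec$ring_spacing
  s_rings <- segment_length / 2 + (seq_len(spec$n_rings) -
                                   (spec$n_rings + 1) / 2) * spec$ring_spacing
  if (stent_len + spec$strut_length > segment_length)
    stop("stent longer than vessel segment")

  V <- NULL; Fc <- NULL
  xs <- ys <- zs <- numeric(0)
  h <- spec$voxel_edge

  add_bar <- function(s_mid, theta, radius, len, wid, thick) {
    # agent grid: axial along the centreline arc, radial, circumferential
    aoff <- grid_centres(len, h)
    toff <- grid_centres(thick, h)
    woff <- grid_centres(wid, h)
    for (a in aoff) {
      fr <- centreline_frame(cl, s_mid + a)
      Uo <- cos(theta) * fr$outward[1, ] + sin(theta) * fr$binormal[1, ]
      Wc <- -sin(theta) * fr$outward[1, ] + cos(theta) * fr$binormal[1, ]
      for (t in toff) for (w in woff) {
        p <- fr$point[1, ] + (radius + t) * Uo + w * Wc
        xs <<- c(xs, p[1]); ys <<- c(ys, p[2]); zs <<- c(zs, p[3])
      }
    }
    # surface box: corners from the same parametrisation
    corn <- matrix(0, 8, 3)
    k <- 1
    for (a in c(-len / 2, len / 2)) {
      fr <- centreline_frame(cl, s_mid + a)
      Uo <- cos(theta) * fr$outward[1, ] + sin(theta) * fr$binormal[1, ]
      Wc <- -sin(theta) * fr$outward[1, ] + cos(theta) * fr$binormal[1, ]
      for (t in c(-thick / 2, thick / 2)) for (w in c(-wid / 2, wid / 2)) {
        corn[k, ] <- fr$point[1, ] + (radius + t) * Uo + w * Wc
        k <- k + 1
      }
    }
    off <- if (is.null(V)) 0L else nrow(V)
    V <<- rbind(V, corn)
    Fc <<- rbind(Fc, box_faces() + off)
  }

  for (i in seq_len(spec$n_rings)) {
    th0 <- (i %% 2) * pi / spec$struts_per_ring
    for (j in seq_len(spec$struts_per_ring)) {
      theta <- th0 + (j - 1) * 2 * pi / spec$struts_per_ring
      add_bar(s_rings[i], theta, spec$target_radius[i],
              spec$strut_length, spec$strut_width, spec$strut_thickness)
    }
    if (spec$connectors == "alternating" && i < spec$n_rings) {
      theta <- th0 + pi / spec$struts_per_ring
      add_bar((s_rings[i] + s_rings[i + 1]) / 2, theta,
              mean(spec$target_radius[i + 0:1]),
              spec$ring_spacing - spec$strut_length,
              spec$strut_width / 2, spec$strut_thickness / 2)
    }
  }

  agents <- new_agents(xs, ys, zs, r = h / 2, kind = "STENT", mobile = FALSE)
  list(mesh = list(vertices = V, faces = Fc), agents = agents, spec = spec)
}

# symmetric grid of cell centres at pitch h spanning a length L
grid_centres <- function(L, h) {
  n <- max(1L, round(L / h))
  (seq_len(n) - (n + 1) / 2) * h
}

# 12 triangles of a unit box given 8 corners ordered (t,w) minor within a
box_faces <- function() {
  # corners: 1=(a-,t-,w-) 2=(a-,t-,w+) 3=(a-,t+,w-) 4=(a-,t+,w+)
  #          5=(a+,t-,w-) 6=(a+,t-,w+) 7=(a+,t+,w-) 8=(a+,t+,w+)
  matrix(c(1, 3, 2, 2, 3, 4,    # a- face
           5, 6, 7, 6, 8, 7,    # a+ face
           1, 2, 5, 2, 6, 5,    # t- face
           3, 7, 4, 4, 7, 8,    # t+ face
           1, 5, 3, 3, 5, 7,    # w- face
           2, 4, 6, 4, 8, 6),   # w+ face
         ncol = 3, byrow = TRUE)
}

#' Fill a watertight surface mesh with stent agents
#'
#' One STENT agent per cubic voxel whose centre lies inside the mesh;
#' agent radius is half the voxel edge (each agent represents a
#' `voxel_edge^3` volume of stent material).
#'
#' @param mesh list with `vertices` (n x 3) and `faces` (m x 3,
#'   1-based) of a watertight triangulated surface.
#' @param voxel_edge voxel edge (mm).
#' @return STENT agent table (immobile).
#' @export
fill_stent_mesh <- function(mesh, voxel_edge = 0.03) {
  V <- as.matrix(mesh$vertices)
  Fc <- as.matrix(mesh$faces)
  storage.mode(Fc) <- "integer"
  check_watertight(Fc)
  lo <- apply(V, 2, min)
  hi <- apply(V, 2, max)
  n <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_edge - 1e-9)))
  gx <- lo[1] + (seq_len(n[1]) - 0.5) * voxel_edge
  gy <- lo[2] + (seq_len(n[2]) - 0.5) * voxel_edge
  gz <- lo[3] + (seq_len(n[3]) - 0.5) * voxel_edge
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  inside <- cpp_points_in_mesh(V, Fc, pts)
  p <- pts[inside, , drop = FALSE]
  new_agents(p[, 1], p[, 2], p[, 3], r = voxel_edge / 2, kind = "STENT",
             mobile = FALSE)
}

check_watertight <- function(Fc) {
  e <- rbind(Fc[, c(1, 2)], Fc[, c(2, 3)], Fc[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2))
    stop("mesh is not watertight: ", sum(cnt != 2),
         " edges are not shared by exactly two triangles")
  invisible(TRUE)
}
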