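#' Extract a histology-style cross-section from a simulation state
#'
#' Cuts the vessel with a plane normal to the local centreline tangent
#' at the given arc-length position. Agents within the slab are
#' projected onto the plane; the lumen contour is traced as the
#' zero-level of the signed distance to the nearest agent surface
#' (wall, ECM and stent material all count as tissue), and strut
#' landmarks are the cluster centroids of stent agents in the slab,
#' labelled A, B, ... clockwise starting from the epicardial
#' (outer-curve) direction at 12 o'clock.
#'
#' Section coordinates: `up` points epicardially, `right` along the
#' torus axis; both in mm.
#'
#' @param state a `sim_state` (or an agent table carrying a
#'   `vessel_spec` attribute).
#' @param position arc length along the centreline (mm).
#' @param slab slab thickness (mm); about one histology section.
#' @param grid in-plane sampling pitch for the lumen contour (mm).
#' @return object of class `section_metrics`: `lumen` (closed contour,
#'   n x 2), `struts` (data frame id/up/right), `position`, `slab`.
#' @export
extract_section <- function(state, position, slab = 0.06, grid = 0.008) {
  if (inherits(state, "sim_state")) {
    agents <- state$agents
    spec <- state$spec
  } else {
    agents <- state
    spec <- attr(agents, "vessel_spec")
  }
  stopifnot(position >= 0, position <= spec$segment_length,
            slab >= 2 * min(agents$r))
  fr <- centreline_frame(spec, position)
  P <- fr$point[1, ]; Tg <- fr$tangent[1, ]
  up <- fr$outward[1, ]; right <- fr$binormal[1, ]
  d <- cbind(agents$x - P[1], agents$y - P[2], agents$z - P[3])
  ax <- d %*% Tg
  cu <- d %*% up
  cr <- d %*% right
  insl <- abs(ax) <= slab / 2 + agents$r

  solid <- which(insl)
  if (!length(solid)) stop("no agents intersect the section at ", position)
  ext <- max(abs(c(cu[solid], cr[solid]))) + max(agents$r) + 4 * grid
  gx <- seq(-ext, ext, by = grid)
  field <- matrix(Inf, length(gx), length(gx))
  # slab projection as in histology: each agent contributes the disc it
  # presents anywhere within the slab (distance taken to the nearest slab
  # face, zero if the centre lies inside the slab)
  axd <- pmax(abs(ax) - slab / 2, 0)
  for (i in solid) {
    ri <- agents$r[i]
    if (axd[i] >= ri) next
    jx <- which(abs(gx - cu[i]) <= ri + 2 * grid)
    jy <- which(abs(gx - cr[i]) <= ri + 2 * grid)
    if (!length(jx) || !length(jy)) next
    dd <- sqrt(outer((gx[jx] - cu[i])^2, (gx[jy] - cr[i])^2, "+") +
                 axd[i]^2) - ri
    field[jx, jy] <- pmin(field[jx, jy], dd)
  }
  field[!is.finite(field)] <- 10 * ext

  # tissue occupancy with a morphological closing at half the agent scale:
  # a plane through packed spheres cuts disconnected discs, the closing
  # restores the contiguous tissue cross-section
  mask <- field <= 0
  k <- max(1L, ceiling(0.5 * stats::median(agents$r[solid]) / grid))
  mask <- close_mask2d(mask, k)
  occ <- matrix(as.numeric(mask), nrow(mask), ncol(mask))

  cl <- contourLines(gx, gx, occ, levels = 0.5)
  if (!length(cl)) stop("no lumen contour found at position ", position)
  seed <- c(0, 0)
  if (interp_field(gx, occ, seed) > 0.5) {
    sm <- which(field == max(field), arr.ind = TRUE)[1, ]
    seed <- c(gx[sm[1]], gx[sm[2]])
  }
  encl <- vapply(cl, function(cc)
    point_in_polygon(seed, cbind(cc$x, cc$y)), logical(1))
  if (!any(encl)) stop("lumen contour does not enclose the centreline at ",
                       position)
  areas <- vapply(cl, function(cc) abs(shoelace(cbind(cc$x, cc$y))),
                  numeric(1))
  pick <- which(encl)[which.min(areas[encl])]
  lumen <- cbind(cl[[pick]]$x, cl[[pick]]$y)

  sidx <- which(insl & agents$kind == "STENT" & abs(ax) <= slab / 2)
  struts <- data.frame(id = character(0), up = numeric(0),
                       right = numeric(0))
  if (length(sidx)) {
    pts <- cbind(cu[sidx], cr[sidx])
    if (length(sidx) == 1L) {
      cent <- pts
    } else {
      hc <- hclust(dist(pts), method = "single")
      grp <- cutree(hc, h = 0.08)
      cent <- do.call(rbind, lapply(split(seq_along(grp), grp), function(g)
        colMeans(pts[g, , drop = FALSE])))
    }
    key <- atan2(cent[, 2], cent[, 1])   # clockwise from 12 o'clock (up)
    key[key < 0] <- key[key < 0] + 2 * pi
    ord <- order(key)
    struts <- data.frame(id = LETTERS[seq_along(ord)],
                         up = cent[ord, 1], right = cent[ord, 2],
                         stringsAsFactors = FALSE)
  }
  structure(list(position = position, slab = slab, lumen = lumen,
                 contours = lapply(cl, function(cc) cbind(cc$x, cc$y)),
                 struts = struts,
                 n_struts = nrow(struts)),
            class = "section_metrics")
}

#' @export
print.section_metrics <- function(x, ...) {
  cat("<section_metrics> s =", x$position, "mm,", x$n_struts,
      "struts, lumen area", signif(abs(shoelace(x$lumen)), 4), "mm^2\n")
  invisible(x)
}

# 2D morphological closing with a square structuring element of radius k
close_mask2d <- function(m, k) {
  shift2 <- function(a, dx, dy, fill) {
    out <- matrix(fill, nrow(a), ncol(a))
    sx <- max(1, 1 + dx):min(nrow(a), nrow(a) + dx)
    sy <- max(1, 1 + dy):min(ncol(a), ncol(a) + dy)
    out[sx, sy] <- a[sx - dx, sy - dy]
    out
  }
  dil <- m
  for (dx in -k:k) for (dy in -k:k)
    if (dx || dy) dil <- dil | shift2(m, dx, dy, FALSE)
  ero <- dil
  for (dx in -k:k) for (dy in -k:k)
    if (dx || dy) ero <- ero & shift2(dil, dx, dy, TRUE)
  ero | m
}

interp_field <- function(gx, field, p) {
  ix <- findInterval(p[1], gx)
  iy <- findInterval(p[2], gx)
  ix <- min(max(ix, 1L), length(gx))
  iy <- min(max(iy, 1L), length(gx))
  field[ix, iy]
}

shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * A)
}

point_in_polygon <- function(p, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  crossing <- ((y > p[2]) != (y[j] > p[2])) &
    (p[1] < (x[j] - x) * (p[2] - y) / (y[j] - y) + x)
  sum(crossing) %% 2 == 1
}

#' Per-strut neointimal thickness
#'
#' For every strut landmark, casts a ray from the strut centre toward
#' the lumen centroid and measures the distance to the first lumen
#' contour intersection, minus the strut half-thickness: the thickness
#' of neointima covering that strut.
#'
#' @param section a `section_metrics`.
#' @param strut_half_thickness half the radial strut thickness (mm).
#' @return data frame with `id`, `thickness` (mm) and `flagged`
#'   (TRUE when the direct ray missed the contour and the nearest
#'   contour vertex distance was used instead).
#' @export
ni_thickness_per_strut <- function(section, strut_half_thickness = 0.045) {
  stopifnot(inherits(section, "section_metrics"))
  if (!nrow(section$struts)) stop("section has no strut landmarks")
  cen <- polygon_centroid(section$lumen)
  # the tissue surface is the nearest boundary crossing along the ray: for
  # a bare strut that is its own profile (thickness ~ 0), for a covered
  # strut the neointimal surface above it
  bounds <- section$contours
  if (is.null(bounds)) bounds <- list(section$lumen)
  out <- lapply(seq_len(nrow(section$struts)), function(i) {
    p0 <- c(section$struts$up[i], section$struts$right[i])
    dirv <- cen - p0
    nd <- sqrt(sum(dirv^2))
    dirv <- dirv / max(nd, 1e-12)
    t_hit <- min(vapply(bounds, function(b) ray_polyline(p0, dirv, b),
                        numeric(1)))
    flagged <- FALSE
    if (!is.finite(t_hit)) {
      dd <- sqrt((section$lumen[, 1] - p0[1])^2 +
                   (section$lumen[, 2] - p0[2])^2)
      t_hit <- min(dd)
      flagged <- TRUE
    }
    data.frame(id = section$struts$id[i],
               thickness = t_hit - strut_half_thickness,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# first positive ray-parameter intersection with a closed polyline
ray_polyline <- function(p0, dirv, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  den <- dirv[1] * (-ey) - dirv[2] * (-ex)
  wx <- a[, 1] - p0[1]; wy <- a[, 2] - p0[2]
  t <- (wx * (-ey) - wy * (-ex)) / den
  u <- (dirv[1] * wy - dirv[2] * wx) / den
  ok <- is.finite(t) & t > 1e-9 & u >= -1e-12 & u <= 1 + 1e-12
  if (!any(ok)) return(Inf)
  min(t[ok])
}

#' Signed neointimal area of a section
#'
#' The neointimal (NI) area is the area of the polygon through the
#' strut centres (in angular order) minus the lumen area; lumen
#' regions lying outside the strut polygon reduce the NI area (counted
#' negatively), so the NI area itself can be negative. The relative NI
#' area is NI area divided by the strut-polygon area.
#'
#' @param section a `section_metrics` with at least 3 struts.
#' @return list with `ni_area` (mm^2, signed), `relative` (fraction),
#'   `strut_polygon_area`, `lumen_area`.
#' @export
ni_area <- function(section) {
  stopifnot(inherits(section, "section_metrics"))
  if (nrow(section$struts) < 3)
    stop("NI area undefined: section at ", section$position,
         " mm has fewer than 3 struts")
  poly <- cbind(section$struts$up, section$struts$right)
  A_struts <- abs(shoelace(poly))
  A_lumen <- abs(shoelace(section$lumen))
  ni <- A_struts - A_lumen
  list(ni_area = ni, relative = ni / A_struts,
       strut_polygon_area = A_struts, lumen_area = A_lumen)
}

#' Build a section from externally supplied contours
#'
#' Lets histology tracings (CSV polylines) be compared with simulated
#' sections using the same metric code.
#'
#' @param lumen data frame or CSV path with columns `up`, `right` (mm):
#'   the closed lumen contour.
#' @param struts data frame or CSV path with columns `id`, `up`,
#'   `right`: strut centre landmarks.
#' @param position nominal arc-length position (mm).
#' @return a `section_metrics`.
#' @export
section_from_contours <- function(lumen, struts, position = NA_real_) {
  if (is.character(lumen)) lumen <- read.csv(lumen)
  if (is.character(struts)) struts <- read.csv(struts)
  stopifnot(all(c("up", "right") %in% names(lumen)),
            all(c("id", "up", "right") %in% names(struts)))
  structure(list(position = position, slab = NA_real_,
                 lumen = cbind(lumen$up, lumen$right),
                 struts = data.frame(id = as.character(struts$id),
                                     up = struts$up, right = struts$right,
                                     stringsAsFactors = FALSE),
                 n_struts = nrow(struts)),
            class = "section_metrics")
}

#' Write section metrics to CSV (+ JSON summary)
#' @param section a `section_metrics`.
#' @param prefix output prefix; writes `<prefix>_lumen.csv`,
#'   `<prefix>_struts.csv`, `<prefix>_summary.json`.
#' @param strut_half_thickness passed to [ni_thickness_per_strut()].
#' @export
write_section_metrics <- function(section, prefix,
                                  strut_half_thickness = 0.045) {
  write.csv(data.frame(up = section$lumen[, 1], right = section$lumen[, 2]),
            paste0(prefix, "_lumen.csv"), row.names = FALSE)
  th <- if (nrow(section$struts)) ni_thickness_per_strut(
    section, strut_half_thickness) else NULL
  st <- section$struts
  if (!is.null(th)) st$thickness <- th$thickness
  write.csv(st, paste0(prefix, "_struts.csv"), row.names = FALSE)
  summ <- list(position = section$position, n_struts = section$n_struts)
  if (section$n_struts >= 3) summ <- c(summ, ni_area(section))
  jsonlite::write_json(summ, paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
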