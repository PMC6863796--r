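#' Read a triangulated surface mesh (ASCII STL, OBJ or PLY)
#'
#' Minimal readers for the common ASCII mesh interchange formats, enough
#' to load a deployed-stent surface for [fill_stent_mesh()]. STL
#' vertices are merged on exact coordinate equality.
#'
#' @param path mesh file; format chosen by extension (.stl, .obj, .ply).
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_surface_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl_ascii(path),
         obj = read_obj(path),
         ply = read_ply_ascii(path),
         stop("unsupported mesh format: .", ext))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices found; binary STL is not supported")
  m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- paste(m[, 1], m[, 2], m[, 3])
  uk <- !duplicated(key)
  verts <- m[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
    as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  list(vertices = verts, faces = faces)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("not an ASCII PLY file")
  nv <- as.integer(sub(".*vertex\\s+", "",
                       grep("element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "",
                       grep("element face", lines, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(
    strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
    function(p) as.integer(p[2:4]) + 1L))
  list(vertices = verts, faces = faces)
}

#' Write a mesh as ASCII STL
#' @param mesh list with `vertices`, `faces`.
#' @param path output path.
#' @export
write_stl_ascii <- function(mesh, path) {
  V <- as.matrix(mesh$vertices)
  Fc <- as.matrix(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid stentsim", con)
  for (i in seq_len(nrow(Fc))) {
    a <- V[Fc[i, 1], ]; b <- V[Fc[i, 2], ]; d <- V[Fc[i, 3], ]
    n <- c((b[2] - a[2]) * (d[3] - a[3]) - (b[3] - a[3]) * (d[2] - a[2]),
           (b[3] - a[3]) * (d[1] - a[1]) - (b[1] - a[1]) * (d[3] - a[3]),
           (b[1] - a[1]) * (d[2] - a[2]) - (b[2] - a[2]) * (d[1] - a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("      vertex %g %g %g", d[1], d[2], d[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid stentsim", con)
  invisible(path)
}

#' Write a scalar voxel field as legacy-ASCII VTK structured points
#' @param field numeric vector of length `prod(dims)` (x fastest).
#' @param dims integer c(nx, ny, nz).
#' @param origin grid origin (mm).
#' @param spacing voxel edge (mm).
#' @param path output `.vtk` file.
#' @param name scalar field name.
#' @export
write_field_vtk <- function(field, dims, origin, spacing, path,
                            name = "field") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "stentsim field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", spacing, spacing, spacing),
               sprintf("POINT_DATA %d", prod(dims)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6g", field), con)
  invisible(path)
}
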