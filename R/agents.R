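#' @keywords internal
AGENT_KINDS <- c("SMC", "IEL_SMC", "EEL_SMC", "ECM", "STENT")

#' Construct an agent table
#'
#' Agents are rows of a data frame: position (mm), rest radius (mm),
#' kind (SMC, IEL_SMC, EEL_SMC, ECM, STENT), SMC phenotype (contractile
#' or synthetic; NA for ECM/stent), mechanical state (bond strain, wall
#' shear stress), the cell-cycle clock (hours) and bookkeeping flags.
#'
#' @param x,y,z agent centre coordinates (mm).
#' @param r rest radius (mm).
#' @param kind agent kind, recycled.
#' @param phenotype SMC phenotype, recycled; NA for non-SMC kinds.
#' @param mobile logical; FALSE pins an agent (stent material, clamped
#'   vessel ends).
#' @return data frame of class `agents`.
#' @export
new_agents <- function(x, y, z, r, kind = "SMC", phenotype = NA_character_,
                       mobile = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n == 0L) {
    a <- data.frame(id = integer(0), kind = character(0),
                    phenotype = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), r = numeric(0), strain = numeric(0),
                    overlap = numeric(0), strain_lamina = numeric(0),
                    wss = numeric(0), r0 = numeric(0),
                    cycle_clock = numeric(0), producing_ecm = logical(0),
                    arrested = logical(0), lamina_ruptured = logical(0),
                    lumen_facing = logical(0),
                    mobile = logical(0), cnx = numeric(0), cny = numeric(0),
                    cnz = numeric(0), stringsAsFactors = FALSE)
    class(a) <- c("agents", "data.frame")
    return(a)
  }
  kind <- rep_len(as.character(kind), n)
  stopifnot(all(kind %in% AGENT_KINDS))
  phenotype <- rep_len(as.character(phenotype), n)
  phenotype[kind %in% c("ECM", "STENT")] <- NA_character_
  a <- data.frame(
    id = seq_len(n),
    kind = kind,
    phenotype = phenotype,
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    r = rep_len(as.numeric(r), n),
    strain = 0, overlap = 0, strain_lamina = 0, wss = 0,
    r0 = rep_len(as.numeric(r), n),
    cycle_clock = 0,
    producing_ecm = FALSE,
    arrested = FALSE,
    lamina_ruptured = FALSE,
    lumen_facing = FALSE,
    mobile = rep_len(as.logical(mobile), n),
    cnx = 0, cny = 0, cnz = 0,  # planar-constraint normal (0 = free)
    stringsAsFactors = FALSE
  )
  class(a) <- c("agents", "data.frame")
  a
}

#' @export
print.agents <- function(x, ...) {
  cat("<agents> ", nrow(x), " agents\n", sep = "")
  print(table(x$kind))
  invisible(x)
}

# integer interaction code used by the C++ force kernels:
# 0 plain, 1 IEL-covered, 2 EEL-covered, -1 stent (repulsion-only)
lamina_code <- function(agents) {
  code <- integer(nrow(agents))
  code[agents$kind == "IEL_SMC"] <- 1L
  code[agents$kind == "EEL_SMC"] <- 2L
  code[agents$kind == "STENT"] <- -1L
  code
}

# append rows, reassigning ids
bind_agents <- function(a, b) {
  stopifnot(identical(names(a), names(b)))
  out <- rbind(as.data.frame(a), as.data.frame(b))
  out$id <- seq_len(nrow(out))
  class(out) <- c("agents", "data.frame")
  out
}

#' Write agents to a columnar CSV file
#'
#' Columns: id, kind, phenotype, x, y, z, r, strain, wss.
#' @param agents agent table.
#' @param path output file.
#' @export
write_agents_csv <- function(agents, path) {
  cols <- c("id", "kind", "phenotype", "x", "y", "z", "r", "strain", "wss")
  write.csv(as.data.frame(agents)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read agents from a CSV written by [write_agents_csv()]
#' @param path CSV file.
#' @return agent table.
#' @export
read_agents_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  new_agents(d$x, d$y, d$z, d$r, kind = d$kind, phenotype = d$phenotype)
}

#' Write agents as legacy-ASCII VTK poly-data (points + radius scalar)
#' @param agents agent table.
#' @param path output `.vtk` file.
#' @export
write_agents_vtk <- function(agents, path) {
  n <- nrow(agents)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "stentsim agents", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.6f %.6f %.6f", agents$x, agents$y, agents$z), con)
  writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS radius float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6f", agents$r), con)
  writeLines(c("SCALARS kind int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", match(agents$kind, AGENT_KINDS)), con)
  writeLines(c("SCALARS wss float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6f", agents$wss), con)
  invisible(path)
}
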