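#' Export a skull mesh as a legacy VTK unstructured grid
#'
#' Writes an ASCII legacy VTK file with hexahedral cells, the region tag
#' as cell data, and optionally a nodal displacement field as point
#' data, so deformed configurations can be inspected in ParaView or
#' similar viewers.
#'
#' @param mesh A `skull_mesh`.
#' @param file Output path.
#' @param displacement Optional N x 3 displacement field (mm).
#' @param deformed Write displaced coordinates instead of the reference
#'   configuration (requires `displacement`).
#' @return The file path, invisibly.
#' @export
write_vtk <- function(mesh, file, displacement = NULL, deformed = FALSE) {
  stopifnot(inherits(mesh, "skull_mesh"))
  xyz <- mesh$nodes
  if (deformed) {
    if (is.null(displacement)) stop("deformed output requires displacement")
    xyz <- xyz + displacement
  }
  n <- nrow(xyz); m <- nrow(mesh$elements)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "spring-assisted cranioplasty skull mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(xyz, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 9L * m), con)
  utils::write.table(cbind(8L, mesh$elements - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS region int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$region)), con)
  if (!is.null(displacement)) {
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS displacement double"), con)
    utils::write.table(format(displacement, digits = 9, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' Read a legacy VTK unstructured grid written by [write_vtk()]
#'
#' Parses nodes, hexahedral connectivity, the region cell data and any
#' displacement point data back into a basic `skull_mesh` (without the
#' structured-grid bookkeeping, so it supports measurement, assembly
#' and export, but not re-cutting or spring placement).
#'
#' @param file Path of a legacy ASCII VTK unstructured grid.
#' @return A list of class `skull_mesh` with an attached `displacement`
#'   attribute when the file carries one.
#' @export
read_vtk <- function(file) {
  lines <- readLines(file)
  grab <- function(pattern) grep(pattern, lines)[1]
  np <- as.integer(strsplit(lines[grab("^POINTS")], " ")[[1]][2])
  p0 <- grab("^POINTS")
  nodes <- matrix(scan(text = lines[(p0 + 1):(p0 + np)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  c0 <- grab("^CELLS")
  nc <- as.integer(strsplit(lines[c0], " ")[[1]][2])
  cells <- matrix(scan(text = lines[(c0 + 1):(c0 + nc)], quiet = TRUE),
                  ncol = 9, byrow = TRUE)
  if (any(cells[, 1] != 8)) stop("only hexahedral cells are supported")
  elements <- matrix(as.integer(cells[, -1] + 1L), ncol = 8)
  r0 <- grab("^SCALARS region")
  region <- factor(skull_regions()[as.integer(
    lines[(r0 + 2):(r0 + 1 + nc)])], levels = skull_regions())
  disp <- NULL
  d0 <- grab("^VECTORS displacement")
  if (!is.na(d0))
    disp <- matrix(scan(text = lines[(d0 + 1):(d0 + np)], quiet = TRUE),
                   ncol = 3, byrow = TRUE)
  mesh <- structure(list(nodes = nodes, elements = elements,
                         region = region,
                         base_nodes = which(nodes[, 3] < 1e-6),
                         outer_nodes = seq_len(np),
                         midline_cut_edges = NULL,
                         osteotomy_applied = NA, grid = NULL,
                         params = NULL), class = "skull_mesh")
  attr(mesh, "displacement") <- disp
  mesh
}

#' Export the outer skull surface as ASCII STL
#'
#' Writes the outer-surface quadrilaterals of the shell (split into
#' triangles) for quick 3D viewing; interior and cut faces are omitted.
#'
#' @param mesh A `skull_mesh`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_stl <- function(mesh, file) {
  stopifnot(inherits(mesh, "skull_mesh"))
  # outer face of each hex: local nodes 5-8 (the outer sheet)
  quads <- mesh$elements[, 5:8, drop = FALSE]
  keep <- matrix(quads %in% mesh$outer_nodes, nrow(quads))
  quads <- quads[rowSums(keep) == 4L, , drop = FALSE]
  tris <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("solid skull", con)
  for (r in seq_len(nrow(tris))) {
    p <- mesh$nodes[tris[r, ], , drop = FALSE]
    nrm <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
               (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
             (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
               (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
             (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
               (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) next  # degenerate sliver at a pole
    nrm <- nrm / nn
    writeLines(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
               con)
    writeLines("    outer loop", con)
    writeLines(sprintf("      vertex %g %g %g", p[, 1], p[, 2], p[, 3]), con)
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid skull", con)
  invisible(file)
}
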