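#' @include microfe-solve.R
NULL

#' Export a solved model as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK with hexahedral cells, nodal displacement vectors and
#' the vertical nodal reaction as point data; readable by standard VTK
#' viewers.
#'
#' @param model an [FEModel-class].
#' @param solution the matching [FESolution-class].
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
exportMesh <- function(model, solution, path) {
  stopifnot(is(model, "FEModel"), is(solution, "FESolution"))
  h <- model@elementSizeUm / 1000
  coords <- model@nodeLattice * h
  nn <- nrow(coords)
  nel <- ncol(model@connectivity)
  Ke <- hex8ElementMatrix(model@material, model@elementSizeUm)
  u <- as.vector(t(solution@displacements))
  w <- .feMatvec(model@connectivity, Ke, nn, u)
  reactZ <- numeric(nn)
  constrained <- sort(unique(c(model@bc@supportNodesA,
                               model@bc@supportNodesB,
                               model@bc@loadNodes)))
  reactZ[constrained] <- w[3L * (constrained - 1L) + 3L]
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) format(x, digits = 17, scientific = FALSE,
                            trim = TRUE)
  writeLines(c("# vtk DataFile Version 3.0",
               "voxel micro-FE bending model", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nn, "double")), con)
  writeLines(paste(fmt(coords[, 1]), fmt(coords[, 2]), fmt(coords[, 3])),
             con)
  writeLines(paste("CELLS", nel, nel * 9L), con)
  cz <- model@connectivity - 1L  # VTK is 0-based; corner order matches
  writeLines(paste(8L, cz[1, ], cz[2, ], cz[3, ], cz[4, ], cz[5, ],
                   cz[6, ], cz[7, ], cz[8, ]), con)
  writeLines(paste("CELL_TYPES", nel), con)
  writeLines(as.character(rep(12L, nel)), con)
  writeLines(paste("POINT_DATA", nn), con)
  writeLines("VECTORS displacement double", con)
  dd <- solution@displacements
  writeLines(paste(fmt(dd[, 1]), fmt(dd[, 2]), fmt(dd[, 3])), con)
  writeLines(c("SCALARS vertical_reaction double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(fmt(reactZ), con)
  invisible(path)
}

# Minimal legacy-VTK reader used to verify exports round-trip.
.readVTKLegacy <- function(path) {
  lines <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- matrix(unlist(lapply(lines[(ip + 1):(ip + np)], num)),
                ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ncell <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- matrix(unlist(lapply(lines[(ic + 1):(ic + ncell)], num)),
                  ncol = 9, byrow = TRUE)[, -1, drop = FALSE] + 1
  iv <- grep("^VECTORS displacement", lines)[1]
  disp <- matrix(unlist(lapply(lines[(iv + 1):(iv + np)], num)),
                 ncol = 3, byrow = TRUE)
  list(points = pts, cells = cells, displacement = disp)
}
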