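#' @include microfe-element.R
NULL

# Corner offsets of the standard hexahedron order along axes 1..3.
.hexOffsets <- cbind(
  dx = c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
  dy = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
  dz = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))

# Voxel-conversion meshing: every TRUE voxel becomes one cube element;
# nodes are the distinct voxel corners.  Returns 8 x nel connectivity
# (1-based node ids) and the nNodes x 3 table of 0-based lattice corner
# coordinates.
.meshFromMask <- function(grid) {
  d <- dim(grid)
  vox <- which(grid)
  if (length(vox) == 0L) stop("mask contains no bone voxels")
  vi <- arrayInd(vox, d)
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L; nz1 <- d[3] + 1L
  lat <- matrix(0L, nrow = length(vox), ncol = 8)
  for (a in 1:8) {
    cx <- vi[, 1] - 1L + .hexOffsets[a, 1]
    cy <- vi[, 2] - 1L + .hexOffsets[a, 2]
    cz <- vi[, 3] - 1L + .hexOffsets[a, 3]
    lat[, a] <- 1L + cx + nx1 * (cy + ny1 * cz)
  }
  used <- logical(nx1 * ny1 * nz1)
  used[lat] <- TRUE
  nodeId <- cumsum(used)          # dense renumbering of used corners
  conn <- matrix(0L, nrow = 8, ncol = length(vox))
  for (a in 1:8) conn[a, ] <- as.integer(nodeId[lat[, a]])
  usedIdx <- which(used) - 1L     # back to 0-based lattice coordinates
  cz <- usedIdx %/% (nx1 * ny1)
  rem <- usedIdx %% (nx1 * ny1)
  cy <- rem %/% nx1
  cx <- rem %% nx1
  list(conn = conn, nodes = cbind(cx, cy, cz))
}

# Bottom-most (or top-most) bone-surface corner nodes in an axis-1 band of
# element columns.  xVox is the plane position in voxel units; halfwidth in
# voxels selects element columns whose centers fall within the band.
.contactNodes <- function(grid, meshNodes, nodeLookup, xVox, halfwidth,
                          top = FALSE) {
  d <- dim(grid)
  ci <- seq_len(d[1]) - 0.5
  cols <- which(abs(ci - xVox) <= halfwidth + 1e-9)
  if (length(cols) == 0L) return(integer())
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L
  ids <- integer(0)
  sub <- grid[cols, , , drop = FALSE]
  hit <- which(sub, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(integer())
  key <- paste(hit[, 1], hit[, 2])
  pick <- if (top) tapply(hit[, 3], key, max) else tapply(hit[, 3], key, min)
  info <- do.call(rbind, strsplit(names(pick), " "))
  i <- cols[as.integer(info[, 1])]
  j <- as.integer(info[, 2])
  k <- as.integer(pick)
  cz <- if (top) k else k - 1L      # corner plane: top face vs bottom face
  for (dxy in 1:4) {
    dx <- .hexOffsets[dxy, 1]; dy <- .hexOffsets[dxy, 2]
    lat <- 1L + (i - 1L + dx) + nx1 * ((j - 1L + dy) + ny1 * cz)
    ids <- c(ids, nodeLookup[lat])
  }
  sort(unique(ids[ids > 0L]))
}

#' Build a voxel-conversion micro-FE model with bending boundary conditions
#'
#' Converts every bone voxel into a cubic hex8 element and attaches
#' three-point-bending boundary conditions: at each bottom roller the
#' bottom-most bone-surface nodes within `contactHalfwidthVox` voxels of
#' the roller plane (across the full width) have their vertical freedom
#' fixed; the analogous top-surface node band at the load position gets the
#' prescribed vertical displacement.  Minimal stabilizers remove the
#' remaining rigid-body motions: the axis-1 freedom is fixed on support set
#' A and the axis-2 freedom on one node of set A (a rolling-pin
#' idealization — full clamping would overstiffen the model).
#'
#' @param mask a cleaned, connected [BoneMask-class].
#' @param material a [Material-class] (default E = 10 GPa, nu = 0.3).
#' @param crop a [SpanCrop-class] giving roller and load positions (mm, in
#'   the same frame as the mask origin).
#' @param contactHalfwidthVox contact band half-width in voxels
#'   (default 1).
#' @param prescribedDisplacementMm vertical displacement at the load nodes
#'   (default -0.01 mm).
#' @return an [FEModel-class].
#' @export
buildModel <- function(mask, material = bonefe::material(), crop,
                       contactHalfwidthVox = 1,
                       prescribedDisplacementMm = -0.01) {
  stopifnot(is(mask, "BoneMask"), is(crop, "SpanCrop"))
  validObject(crop)
  h <- mask@voxelSizeUm / 1000
  mesh <- .meshFromMask(mask@grid)
  d <- dim(mask@grid)
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L; nz1 <- d[3] + 1L
  nodeLookup <- integer(nx1 * ny1 * nz1)
  latAll <- 1L + mesh$nodes[, 1] + nx1 * (mesh$nodes[, 2] +
                                          ny1 * mesh$nodes[, 3])
  nodeLookup[latAll] <- seq_len(nrow(mesh$nodes))
  toVox <- function(posMm) (posMm - mask@originMm[1]) / h
  rollers <- sort(crop@rollerPositionsMm)
  supA <- .contactNodes(mask@grid, mesh$nodes, nodeLookup,
                        toVox(rollers[1]), contactHalfwidthVox)
  supB <- .contactNodes(mask@grid, mesh$nodes, nodeLookup,
                        toVox(rollers[2]), contactHalfwidthVox)
  loadN <- .contactNodes(mask@grid, mesh$nodes, nodeLookup,
                         toVox(crop@loadPositionMm), contactHalfwidthVox,
                         top = TRUE)
  if (length(supA) == 0L)
    stop("geometry error: bone does not reach the roller plane at ",
         rollers[1], " mm")
  if (length(supB) == 0L)
    stop("geometry error: bone does not reach the roller plane at ",
         rollers[2], " mm")
  if (length(loadN) == 0L)
    stop("geometry error: bone does not reach the load plane at ",
         crop@loadPositionMm, " mm")
  bc <- new("BCSet", supportNodesA = supA, supportNodesB = supB,
            stabilizerNodes = supA[1], loadNodes = loadN,
            prescribedDisplacementMm = as.numeric(prescribedDisplacementMm))
  new("FEModel", mask = mask, elementSizeUm = mask@voxelSizeUm,
      material = material, connectivity = mesh$conn,
      nodeLattice = mesh$nodes, bc = bc)
}

# Dirichlet dof list (0-based) and values for a model's BCSet.
.dirichletDofs <- function(model) {
  bc <- model@bc
  zA <- 3L * (bc@supportNodesA - 1L) + 2L
  zB <- 3L * (bc@supportNodesB - 1L) + 2L
  xA <- 3L * (bc@supportNodesA - 1L)
  yS <- 3L * (bc@stabilizerNodes - 1L) + 1L
  zL <- 3L * (bc@loadNodes - 1L) + 2L
  dof <- c(zA, zB, xA, yS, zL)
  val <- c(rep(0, length(zA) + length(zB) + length(xA) + length(yS)),
           rep(bc@prescribedDisplacementMm, length(zL)))
  keep <- !duplicated(dof)
  list(dof = dof[keep], val = val[keep])
}
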