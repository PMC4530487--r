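#' @include constructors.R
NULL

# ---- MetaImage (.mha) ----------------------------------------------------
# Minimal uncompressed MetaImage reader/writer (local, single-file form).
# Doubles on disk so that write -> read round-trips exactly.

.writeMha <- function(grid, voxelSizeMm, dataRangeMax, path) {
  d <- dim(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           "Offset = 0 0 0",
           "CenterOfRotation = 0 0 0",
           paste("ElementSpacing =", paste(format(rep(voxelSizeMm, 3),
                 digits = 17), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("DataRangeMax =", format(dataRangeMax, digits = 17)),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.vector(grid), con, size = 8, endian = "little")
  invisible(path)
}

.readMha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed MetaImage header in ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only single-file (LOCAL) MetaImage volumes are supported")
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
                 MET_USHORT = 2L, MET_UCHAR = 1L,
                 stop("unsupported MetaImage ElementType: ", type))
  what <- if (type %in% c("MET_DOUBLE", "MET_FLOAT")) "numeric"
          else "integer"
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT")
  n <- prod(d)
  raw <- readBin(con, what, n = n, size = size, signed = signed,
                 endian = "little")
  list(grid = array(as.numeric(raw), d), spacingMm = sp,
       dataRangeMax = if (!is.null(hdr[["DataRangeMax"]]))
         as.numeric(hdr[["DataRangeMax"]]) else NA_real_)
}

# ---- public I/O ----------------------------------------------------------

#' Read a grayscale volume
#'
#' Supports MetaImage (`.mha`), NIfTI (`.nii`, `.nii.gz`) and multi-page
#' TIFF stacks (`.tif`, `.tiff`).  Voxel spacing is taken from the file
#' metadata for MetaImage and NIfTI; TIFF carries no physical spacing, so
#' `spacingUm` must be given explicitly — there is no silent default.
#' Anisotropic volumes are rejected: the pipeline assumes isotropic voxels.
#'
#' @param path input file.
#' @param spacingUm voxel spacing in micrometres; required for TIFF,
#'   ignored (with a check) otherwise.
#' @param dataRangeMax maximum representable intensity; default 32767
#'   unless the file records one.
#' @return a [VoxelImage-class].
#' @seealso [writeVolume]
#' @export
readVolume <- function(path, spacingUm = NULL, dataRangeMax = 32767) {
  ext <- tolower(sub(".*?(\\.[a-zA-Z0-9.]+)$", "\\1", basename(path)))
  if (grepl("\\.mha$", ext)) {
    m <- .readMha(path)
    sp <- m$spacingMm * 1000
    if (diff(range(sp)) > 1e-6 * max(sp))
      stop("anisotropic volume in ", path,
           ": the pipeline assumes isotropic voxels")
    drm <- if (is.na(m$dataRangeMax)) dataRangeMax else m$dataRangeMax
    return(voxelImage(m$grid, sp[1], drm))
  }
  if (grepl("\\.nii(\\.gz)?$", ext)) {
    img <- RNifti::readNifti(path)
    # NIfTI spatial units here are mm; pixdim is float32 on disk, so
    # recover the spacing at float precision (~7 significant digits)
    sp <- signif(RNifti::pixdim(img) * 1000, 7)
    if (diff(range(sp)) > 1e-6 * max(sp))
      stop("anisotropic volume in ", path,
           ": the pipeline assumes isotropic voxels")
    grid <- array(as.numeric(img), dim(img))
    return(voxelImage(grid, sp[1], dataRangeMax))
  }
  if (grepl("\\.tiff?$", ext)) {
    if (is.null(spacingUm))
      stop("TIFF stacks carry no voxel spacing: supply `spacingUm` ",
           "(micrometres) explicitly")
    # integer TIFFs come back normalized to [0,1]; scale to the data range
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d2 <- dim(pages[[1]])
    grid <- array(0, c(d2[1], d2[2], length(pages)))
    for (k in seq_along(pages))
      grid[, , k] <- as.numeric(pages[[k]]) * dataRangeMax
    return(voxelImage(grid, spacingUm, dataRangeMax))
  }
  stop("unrecognized volume format: ", path,
       " (expected .mha, .nii[.gz] or .tif)")
}

#' Write a grayscale volume or bone mask
#'
#' MetaImage output stores doubles (masks: 8-bit), so write -> read
#' round-trips the grid and spacing exactly.  NIfTI output goes through
#' RNifti with the spacing in mm.
#'
#' @param img a [VoxelImage-class] or [BoneMask-class].
#' @param path output file ending in `.mha`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(img, path) {
  isMask <- is(img, "BoneMask")
  grid <- if (isMask) img@grid + 0 else img@grid
  drm <- if (isMask) 1 else img@dataRangeMax
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    .writeMha(grid, img@voxelSizeUm / 1000, drm, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    nim <- RNifti::asNifti(grid)
    RNifti::pixdim(nim) <- rep(img@voxelSizeUm / 1000, 3)
    RNifti::writeNifti(nim, path)
  } else {
    stop("unsupported output format for ", path,
         " (use .mha or .nii[.gz])")
  }
  invisible(path)
}

#' Read a bone mask written by [writeVolume]
#'
#' @param path input `.mha` or `.nii[.gz]` file containing 0/1 values.
#' @param spacingUm spacing override (micrometres), usually taken from the
#'   file.
#' @return a [BoneMask-class].
#' @export
readMask <- function(path, spacingUm = NULL) {
  img <- readVolume(path, spacingUm = spacingUm, dataRangeMax = 1)
  boneMask(img@grid > 0.5, img@voxelSizeUm)
}

# ---- preprocessing chain -------------------------------------------------

.rotAxis <- function(axis, deg) {
  th <- deg * pi / 180
  c3 <- cos(th); s3 <- sin(th)
  R <- diag(3)
  a <- setdiff(1:3, axis)
  R[a[1], a[1]] <- c3; R[a[2], a[2]] <- c3
  R[a[1], a[2]] <- -s3; R[a[2], a[1]] <- s3
  R
}

#' Reorient a volume to the bending-test frame
#'
#' Scans must be rotated so that their orientation matches the physical
#' three-point bending setup (axis 1 = roller span, axis 3 = load
#' direction).  Axis-aligned permutations and flips are lossless; an
#' arbitrary rotation (Euler angle triple or a 3x3 rotation matrix) is
#' applied by trilinear resampling about the volume center.
#'
#' @param img a [VoxelImage-class].
#' @param permutation integer permutation of `1:3` (applied first).
#' @param flip logical length-3: reverse the corresponding axis.
#' @param anglesDeg numeric length-3: rotations in degrees about axes 1, 2
#'   and 3, composed in that order; `NULL` for none.
#' @param rotationMatrix 3x3 orthonormal matrix alternative to
#'   `anglesDeg`.
#' @param fill intensity used outside the source volume (default the
#'   volume minimum).
#' @return a [VoxelImage-class] in the new orientation.
#' @export
reorient <- function(img, permutation = c(1L, 2L, 3L),
                     flip = c(FALSE, FALSE, FALSE), anglesDeg = NULL,
                     rotationMatrix = NULL, fill = NULL) {
  stopifnot(is(img, "VoxelImage"))
  if (!identical(sort(as.integer(permutation)), 1:3))
    stop("permutation must be a permutation of 1:3")
  grid <- aperm(img@grid, permutation)
  for (a in 1:3) if (isTRUE(flip[a])) {
    idx <- rev(seq_len(dim(grid)[a]))
    grid <- switch(a, grid[idx, , , drop = FALSE],
                   grid[, idx, , drop = FALSE],
                   grid[, , idx, drop = FALSE])
  }
  out <- voxelImage(grid, img@voxelSizeUm, img@dataRangeMax, img@originMm)
  R <- rotationMatrix
  if (!is.null(anglesDeg)) {
    if (!is.null(R)) stop("give either anglesDeg or rotationMatrix")
    stopifnot(length(anglesDeg) == 3L)
    R <- .rotAxis(3, anglesDeg[3]) %*% .rotAxis(2, anglesDeg[2]) %*%
      .rotAxis(1, anglesDeg[1])
  }
  if (is.null(R)) return(out)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  .resampleRotated(out, R, fill)
}

# Trilinear resampling of img under rotation R about the volume center:
# target voxel center p maps to source point R^T (p - c) + c.
.resampleRotated <- function(img, R, fill = NULL) {
  g <- img@grid
  d <- dim(g)
  if (is.null(fill)) fill <- min(g)
  ctr <- d / 2  # in voxel units (centers at i - 0.5)
  idx <- arrayInd(seq_along(g), d)
  P <- sweep(idx - 0.5, 2, ctr)   # target centers relative to center
  Q <- P %*% R                    # rows: R^T %*% p
  Q <- sweep(Q, 2, ctr, "+") + 0.5  # back to 1-based voxel-center coords
  x0 <- floor(Q)
  fx <- Q - x0
  val <- numeric(nrow(Q))
  acc <- numeric(nrow(Q))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- x0[, 1] + dx; iy <- x0[, 2] + dy; iz <- x0[, 3] + dz
    w <- (if (dx) fx[, 1] else 1 - fx[, 1]) *
         (if (dy) fx[, 2] else 1 - fx[, 2]) *
         (if (dz) fx[, 3] else 1 - fx[, 3])
    inside <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] &
      iz >= 1 & iz <= d[3]
    ixc <- pmin(pmax(ix, 1L), d[1])
    iyc <- pmin(pmax(iy, 1L), d[2])
    izc <- pmin(pmax(iz, 1L), d[3])
    v <- g[cbind(ixc, iyc, izc)]
    v[!inside] <- fill
    acc <- acc + w * v
    val <- val + w
  }
  outGrid <- array(acc, d)
  outGrid[outGrid < 0] <- 0
  outGrid[outGrid > img@dataRangeMax] <- img@dataRangeMax
  voxelImage(outGrid, img@voxelSizeUm, img@dataRangeMax, img@originMm)
}

#' Reduce the resolution of a volume by block averaging
#'
#' Each output voxel is the arithmetic mean of its source block, the
#' standard anti-aliasing reduction, which conserves integrated density
#' (`sum(out) * factor^3 == sum(in)`).  The target spacing must be an
#' integer multiple of the source spacing (25 -> 50 um is factor 2);
#' otherwise resample/reorient first.  Trailing voxels that do not fill a
#' complete block are dropped with a warning.
#'
#' @param img a [VoxelImage-class].
#' @param targetUm target spacing in micrometres (default 50).
#' @return a [VoxelImage-class] at the reduced resolution.
#' @export
downsampleTo <- function(img, targetUm = 50) {
  stopifnot(is(img, "VoxelImage"))
  f <- targetUm / img@voxelSizeUm
  if (abs(f - round(f)) > 1e-9 || round(f) < 1)
    stop("target spacing ", targetUm, " um is not an integer multiple of ",
         img@voxelSizeUm, " um; resample or reorient first")
  f <- as.integer(round(f))
  if (f == 1L) return(img)
  g <- img@grid
  d <- dim(g)
  keep <- (d %/% f) * f
  if (any(keep < d)) {
    warning("dropping ", paste(d - keep, collapse = "/"),
            " trailing voxels that do not fill a complete block")
    g <- g[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
           drop = FALSE]
  }
  for (axis in 1:3) {
    d <- dim(g)
    g <- aperm(g, c(axis, setdiff(1:3, axis)))
    da <- dim(g)
    dim(g) <- c(f, da[1] / f, da[2], da[3])
    g <- colMeans(g)
    g <- aperm(g, order(c(axis, setdiff(1:3, axis))))
  }
  voxelImage(g, targetUm, img@dataRangeMax, img@originMm)
}

#' Segment mineralized bone by a per-mille threshold
#'
#' A voxel is bone iff its intensity is at least
#' `permille / 1000 * reference`, where the reference is the maximum
#' possible value of the storage range (default) or, optionally, the
#' observed image maximum.  The default follows the literal single-
#' threshold convention: 500 per mille of the maximum possible value.
#'
#' @param img a [VoxelImage-class].
#' @param permille threshold in (0, 1000] (default 500).
#' @param reference `"range"` (data-range maximum, default) or
#'   `"observed"` (image maximum).
#' @return a [BoneMask-class].
#' @export
thresholdPermille <- function(img, permille = 500,
                              reference = c("range", "observed")) {
  stopifnot(is(img, "VoxelImage"))
  reference <- match.arg(reference)
  if (!is.numeric(permille) || length(permille) != 1L || permille <= 0 ||
      permille > 1000)
    stop("permille must lie in (0, 1000]")
  ref <- if (reference == "range") img@dataRangeMax else max(img@grid)
  cut <- permille / 1000 * ref
  mask <- img@grid >= cut
  if (!any(mask))
    stop("no voxels at or above ", permille,
         " per mille of the reference value")
  boneMask(mask, img@voxelSizeUm, img@originMm)
}

#' Crop a mask to the bending span
#'
#' Keeps the region between the bottom rollers plus the margin on each
#' side along axis 1, at full extent on the other axes.  Indices are
#' 0-based half-open `[start, end)` with voxel boundaries at multiples of
#' the spacing: rollers at 1.0 and 11.0 mm with a 0.5 mm margin at 50 um
#' give the index range `[10, 230)`.  The mask origin is updated so that
#' roller coordinates keep their physical meaning; cropping twice is
#' idempotent.
#'
#' @param mask a [BoneMask-class].
#' @param crop a [SpanCrop-class].
#' @return the cropped [BoneMask-class].
#' @export
cropToSpan <- function(mask, crop) {
  stopifnot(is(mask, "BoneMask"), is(crop, "SpanCrop"))
  validObject(crop)
  h <- mask@voxelSizeUm / 1000
  nx <- dim(mask@grid)[1]
  extent <- mask@originMm[1] + c(0, nx * h)
  outside <- crop@rollerPositionsMm[crop@rollerPositionsMm < extent[1] |
                                    crop@rollerPositionsMm > extent[2]]
  if (length(outside) > 0)
    stop("roller at ", outside[1], " mm lies outside the volume extent [",
         extent[1], ", ", extent[2], "] mm")
  lo <- min(crop@rollerPositionsMm) - crop@marginMm - mask@originMm[1]
  hi <- max(crop@rollerPositionsMm) + crop@marginMm - mask@originMm[1]
  iLo <- max(0L, as.integer(floor(lo / h + 1e-9)))
  iHi <- min(nx, as.integer(ceiling(hi / h - 1e-9)))
  if (iHi <= iLo)
    stop("crop window [", lo, ", ", hi, ") mm does not intersect the mask")
  g <- mask@grid[(iLo + 1L):iHi, , , drop = FALSE]
  if (!any(g)) stop("crop produced an empty mask")
  origin <- mask@originMm
  origin[1] <- origin[1] + iLo * h
  boneMask(g, mask@voxelSizeUm, origin)
}

#' Keep only the largest connected bone component
#'
#' Face (6-)connectivity.  Floating islands would make the stiffness
#' matrix singular, so everything but the largest component is removed.
#' Size ties are broken in favour of the component containing the smallest
#' linear voxel index (axis 1 fastest), i.e. the lexicographically first
#' seed voxel.
#'
#' @param mask a [BoneMask-class].
#' @return a [BoneMask-class] with a single connected component.
#' @export
largestComponent <- function(mask) {
  stopifnot(is(mask, "BoneMask"))
  labels <- .labelComponents6(as.vector(mask@grid), dim(mask@grid))
  ncomp <- attr(labels, "ncomp")
  if (ncomp <= 1L) return(mask)
  sizes <- tabulate(labels, nbins = ncomp)
  keep <- which(sizes == max(sizes))[1]  # labels ordered by first seed
  g <- array(labels == keep, dim(mask@grid))
  boneMask(g, mask@voxelSizeUm, mask@originMm)
}

#' Run the standard preprocessing chain
#'
#' Fixed order: reorient, reduce resolution by block mean, threshold,
#' crop to the bending span, largest-component cleanup.
#'
#' @param img a [VoxelImage-class].
#' @param crop a [SpanCrop-class].
#' @param targetUm resolution after reduction (default 50).
#' @param permille segmentation threshold (default 500).
#' @param reference threshold reference, see [thresholdPermille].
#' @param ... reorientation arguments forwarded to [reorient].
#' @return a [BoneMask-class] ready for [buildModel].
#' @export
preprocessVolume <- function(img, crop, targetUm = 50, permille = 500,
                             reference = "range", ...) {
  img <- reorient(img, ...)
  img <- downsampleTo(img, targetUm)
  mask <- thresholdPermille(img, permille, reference)
  mask <- cropToSpan(mask, crop)
  largestComponent(mask)
}
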