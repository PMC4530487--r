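#' @include constructors.R
NULL

# Separable Gaussian blur with replicate (nearest) edge handling.  sigma is
# in voxels; kernel truncated at 3 sigma.  A hand-rolled shift-and-add
# convolution: each tap is one vectorized array shift, so the cost is
# O(taps * nvox).
.gaussianBlur3d <- function(arr, sigmaVox) {
  if (sigmaVox <= 0) return(arr)
  rad <- max(1L, ceiling(3 * sigmaVox))
  kern <- stats::dnorm(seq(-rad, rad), sd = sigmaVox)
  kern <- kern / sum(kern)
  d <- dim(arr)
  for (axis in 1:3) {
    n <- d[axis]
    out <- array(0, d)
    for (t in seq_along(kern)) {
      off <- t - rad - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      idx <- switch(axis,
                    arr[src, , , drop = FALSE],
                    arr[, src, , drop = FALSE],
                    arr[, , src, drop = FALSE])
      out <- out + kern[t] * idx
    }
    arr <- out
  }
  arr
}

# Cross-section bone membership by the voxel-center rule: a voxel is bone
# iff its center lies inside the annulus [rInner, rOuter).
.annulusSection <- function(ny, nz, hMm, centerMm, rInnerMm, rOuterMm) {
  yc <- (seq_len(ny) - 0.5) * hMm - centerMm[1]
  zc <- (seq_len(nz) - 0.5) * hMm - centerMm[2]
  r <- sqrt(outer(yc^2, zc^2, "+"))
  r >= rInnerMm & r < rOuterMm
}

#' Generate a synthetic micro-CT femur mid-shaft volume
#'
#' Renders the ideal geometry of a hollow cortical cylinder aligned with
#' axis 1 and centered in the cross-section — optionally with a concentric
#' endosteal woven-bone shell and periosteal thickening, the two geometric
#' signatures of post-ablation bone modeling — into a grayscale volume,
#' then applies Gaussian partial-volume blur followed by additive Gaussian
#' noise clipped to the data range.  Voxel membership follows the
#' voxel-center-inside-surface rule, so with zero blur and noise the bone
#' voxels reproduce the analytic annulus exactly and survive a 500 per
#' mille threshold whenever `boneGrayLevel > 0.5`.
#'
#' The same spec (including seed) always yields a bit-identical volume.
#'
#' @param spec a [PhantomSpec-class].
#' @param padVox background padding around the outer surface in voxels
#'   (default 3).
#' @return a [VoxelImage-class].
#' @examples
#' img <- generateFemurPhantom(phantomSpec(voxelSizeUm = 100,
#'                                         blurSigmaUm = 0, noiseSd = 0))
#' dim(img)
#' @export
generateFemurPhantom <- function(spec, padVox = 3L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@voxelSizeUm / 1000  # mm
  rOuter <- spec@outerRadiusMm + spec@periostealThickeningMm
  rInner <- spec@outerRadiusMm - spec@corticalThicknessMm - spec@wovenBoneMm
  if (rInner < 0)
    stop("phantom sizing error: woven-bone shell thickness ",
         spec@wovenBoneMm, " mm exceeds the medullary radius")
  nx <- max(1L, round(spec@lengthMm / h))
  nyz <- 2L * ceiling(rOuter / h) + 2L * as.integer(padVox)
  if (nx < 1L || nyz < 2L)
    stop("phantom sizing error: lengthMm or outerRadiusMm too small for ",
         "voxel size ", spec@voxelSizeUm, " um")
  center <- rep(nyz * h / 2, 2)
  section <- .annulusSection(nyz, nyz, h, center, rInner, rOuter)
  lvlBone <- spec@boneGrayLevel * spec@dataRangeMax
  lvlBg <- spec@backgroundGrayLevel * spec@dataRangeMax
  slice <- ifelse(section, lvlBone, lvlBg)
  grid <- array(slice, c(nyz, nyz, nx))      # replicate along the shaft
  grid <- aperm(grid, c(3, 1, 2))            # axis 1 = shaft
  grid <- .gaussianBlur3d(grid, spec@blurSigmaUm / spec@voxelSizeUm)
  if (spec@noiseSd > 0) {
    noise <- withr::with_seed(spec@seed,
      stats::rnorm(length(grid), sd = spec@noiseSd * spec@dataRangeMax))
    grid <- grid + array(noise, dim(grid))
  }
  grid[grid < 0] <- 0
  grid[grid > spec@dataRangeMax] <- spec@dataRangeMax
  voxelImage(grid, spec@voxelSizeUm, spec@dataRangeMax)
}

#' Generate a synthetic load-displacement curve
#'
#' Piecewise-linear destructive bending record: elastic slope `k` up to the
#' yield point, reduced plastic slope up to the ultimate point, then a
#' linear drop to `failureDropFraction * ultimateLoad` over 2% of the
#' ultimate displacement.  Sampling is uniform at the displacement step
#' implied by the crosshead speed and the sampling interval; Gaussian force
#' noise is added on top.  Same spec (including seed) gives an identical
#' curve.
#'
#' @param spec a [CurveSpec-class].
#' @param metadata named list stored on the curve.
#' @return a [LoadDisplCurve-class].
#' @examples
#' crv <- generateLoadCurve(curveSpec(stiffnessNPerMm = 100,
#'                                    yieldLoadN = 40, ultimateLoadN = 60))
#' max(forceSamples(crv))
#' @export
generateLoadCurve <- function(spec, metadata = list()) {
  stopifnot(is(spec, "CurveSpec"))
  validObject(spec)
  k <- spec@stiffnessNPerMm
  k2 <- spec@postYieldStiffnessFraction * k
  dy <- spec@yieldLoadN / k
  du <- if (k2 > 0) dy + (spec@ultimateLoadN - spec@yieldLoadN) / k2
        else dy  # zero plastic slope: plateau handled below
  if (k2 == 0) du <- dy * 1.5  # flat plastic plateau of finite extent
  dEnd <- du * 1.02
  step <- spec@displacementRateMmPerMin / 60 * spec@sampleIntervalS
  d <- seq(0, dEnd, by = step)
  if (length(d) < 20L)
    stop("curve would have fewer than 20 samples; decrease ",
         "sampleIntervalS or the loads/stiffness ratio")
  fEnd <- spec@failureDropFraction * spec@ultimateLoadN
  force <- ifelse(d <= dy, k * d,
           ifelse(d <= du,
                  spec@yieldLoadN + k2 * (d - dy),
                  spec@ultimateLoadN -
                    (spec@ultimateLoadN - fEnd) * (d - du) / (dEnd - du)))
  if (spec@noiseSdN > 0) {
    force <- force + withr::with_seed(spec@seed,
      stats::rnorm(length(force), sd = spec@noiseSdN))
  }
  loadDisplCurve(d, force, metadata)
}

#' Sample accessors for a load-displacement curve
#'
#' @param curve a [LoadDisplCurve-class].
#' @return numeric vector of samples.
#' @export
displacementSamples <- function(curve) curve@displacementMm

#' @rdname displacementSamples
#' @export
forceSamples <- function(curve) curve@forceN

#' Generate a synthetic paired treated/control cohort
#'
#' Control-bone values are i.i.d. lognormal with the requested mean and
#' coefficient of variation; the treated side is
#' `control * (1 + effect) * exp(noise)` with lognormal pairwise noise of
#' the requested CV (mean-one).  With zero effect and zero pair noise the
#' treated values equal the controls exactly.
#'
#' @param spec a [PairedCohortSpec-class].
#' @return data.frame with columns `pair`, `control`, `treated`.
#' @examples
#' generatePairedCohort(pairedCohortSpec(treatmentEffect = -0.16,
#'                                       pairNoiseCv = 0))
#' @export
generatePairedCohort <- function(spec) {
  stopifnot(is(spec, "PairedCohortSpec"))
  validObject(spec)
  n <- spec@nPairs
  sdlogC <- sqrt(log1p(spec@controlCv^2))
  mulogC <- log(spec@controlMean) - sdlogC^2 / 2
  sdlogP <- sqrt(log1p(spec@pairNoiseCv^2))
  vals <- withr::with_seed(spec@seed, {
    ctrl <- stats::rlnorm(n, meanlog = mulogC, sdlog = sdlogC)
    noise <- if (sdlogP > 0)
      stats::rlnorm(n, meanlog = -sdlogP^2 / 2, sdlog = sdlogP)
    else rep(1, n)
    list(ctrl = ctrl, noise = noise)
  })
  treated <- vals$ctrl * (1 + spec@treatmentEffect) * vals$noise
  data.frame(pair = seq_len(n), control = vals$ctrl, treated = treated)
}
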