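#' @include AllClasses.R
NULL

#' Construct a VoxelImage
#'
#' @param grid 3D numeric array; axis 1 is the shaft/span direction, axis 3
#'   the vertical load direction.
#' @param voxelSizeUm isotropic voxel spacing in micrometres.
#' @param dataRangeMax maximum representable intensity of the storage
#'   format (default 32767, a signed 16-bit scanner range).
#' @param originMm physical coordinate of the low corner of voxel
#'   `[1,1,1]`.
#' @return a [VoxelImage-class].
#' @examples
#' img <- voxelImage(array(0, c(4, 4, 4)), voxelSizeUm = 25)
#' voxelSize(img)
#' @export
voxelImage <- function(grid, voxelSizeUm, dataRangeMax = 32767,
                       originMm = c(0, 0, 0)) {
  new("VoxelImage", grid = grid, voxelSizeUm = as.numeric(voxelSizeUm),
      dataRangeMax = as.numeric(dataRangeMax),
      originMm = as.numeric(originMm))
}

#' Construct a BoneMask
#'
#' @param grid 3D logical array, TRUE = bone.
#' @param voxelSizeUm isotropic voxel spacing in micrometres.
#' @param originMm physical coordinate of the low corner of voxel
#'   `[1,1,1]`.
#' @return a [BoneMask-class].
#' @export
boneMask <- function(grid, voxelSizeUm, originMm = c(0, 0, 0)) {
  new("BoneMask", grid = grid, voxelSizeUm = as.numeric(voxelSizeUm),
      originMm = as.numeric(originMm))
}

#' Construct a SpanCrop
#'
#' @param rollerPositionsMm the two bottom-roller coordinates along axis 1
#'   (mm, uncropped frame).
#' @param marginMm crop margin beyond each roller (default 0.5).
#' @param loadPositionMm top-roller coordinate; default midpoint of the
#'   rollers.
#' @return a [SpanCrop-class].
#' @examples
#' spanCrop(c(1, 11))           # load at 6 mm
#' @export
spanCrop <- function(rollerPositionsMm, marginMm = 0.5,
                     loadPositionMm = mean(rollerPositionsMm)) {
  new("SpanCrop", rollerPositionsMm = as.numeric(rollerPositionsMm),
      marginMm = as.numeric(marginMm),
      loadPositionMm = as.numeric(loadPositionMm))
}

#' Construct a Material
#'
#' @param youngsModulusGPa tissue Young's modulus in GPa (default 10, the
#'   reference value prescribed in the micro-FE models).
#' @param poissonRatio Poisson's ratio (default 0.3).
#' @return a [Material-class].
#' @export
material <- function(youngsModulusGPa = 10, poissonRatio = 0.3) {
  new("Material", youngsModulusGPa = as.numeric(youngsModulusGPa),
      poissonRatio = as.numeric(poissonRatio))
}

#' Construct a LoadDisplCurve
#'
#' @param displacementMm monotone non-decreasing displacement samples (mm)
#'   starting at 0.
#' @param forceN force samples (N).
#' @param metadata named list (specimen, side, timepoint, ...).
#' @return a [LoadDisplCurve-class].
#' @export
loadDisplCurve <- function(displacementMm, forceN, metadata = list()) {
  new("LoadDisplCurve", displacementMm = as.numeric(displacementMm),
      forceN = as.numeric(forceN), metadata = metadata)
}

#' Specify a synthetic femur mid-shaft phantom
#'
#' Defaults give an untreated control: a plain hollow cortical cylinder,
#' 12 mm long, 2 mm outer radius, 0.6 mm wall, imaged at 25 um with one
#' voxel of partial-volume blur and 2% additive noise.  A treated bone is
#' mimicked by a nonzero endosteal woven-bone shell and/or periosteal
#' thickening.
#'
#' @param lengthMm,outerRadiusMm,corticalThicknessMm cylinder geometry.
#' @param wovenBoneMm endosteal woven-bone shell thickness (mm).
#' @param periostealThickeningMm periosteal new-bone thickness (mm).
#' @param voxelSizeUm scan voxel size.
#' @param boneGrayLevel,backgroundGrayLevel fractions of the data range.
#' @param blurSigmaUm Gaussian blur sigma (um).
#' @param noiseSd additive noise sd as a fraction of the data range.
#' @param dataRangeMax maximum representable intensity.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(lengthMm = 12, outerRadiusMm = 2,
                        corticalThicknessMm = 0.6, wovenBoneMm = 0,
                        periostealThickeningMm = 0, voxelSizeUm = 25,
                        boneGrayLevel = 0.75, backgroundGrayLevel = 0.05,
                        blurSigmaUm = 25, noiseSd = 0.02,
                        dataRangeMax = 32767, seed = 1L) {
  new("PhantomSpec", lengthMm = as.numeric(lengthMm),
      outerRadiusMm = as.numeric(outerRadiusMm),
      corticalThicknessMm = as.numeric(corticalThicknessMm),
      wovenBoneMm = as.numeric(wovenBoneMm),
      periostealThickeningMm = as.numeric(periostealThickeningMm),
      voxelSizeUm = as.numeric(voxelSizeUm),
      boneGrayLevel = as.numeric(boneGrayLevel),
      backgroundGrayLevel = as.numeric(backgroundGrayLevel),
      blurSigmaUm = as.numeric(blurSigmaUm), noiseSd = as.numeric(noiseSd),
      dataRangeMax = as.numeric(dataRangeMax), seed = as.integer(seed))
}

#' Specify a synthetic load-displacement curve
#'
#' Bilinear elastic/plastic response with a terminal failure drop, sampled
#' at the displacement step implied by the crosshead speed (default
#' 0.1 mm/min, the destructive-test speed) and the sampling interval.
#'
#' @param stiffnessNPerMm true elastic stiffness (N/mm).
#' @param yieldLoadN,ultimateLoadN true yield and ultimate loads (N).
#' @param postYieldStiffnessFraction plastic/elastic slope ratio.
#' @param failureDropFraction force retained after failure.
#' @param displacementRateMmPerMin crosshead speed.
#' @param sampleIntervalS sampling interval (s).
#' @param noiseSdN force noise sd (N).
#' @param seed RNG seed.
#' @return a [CurveSpec-class].
#' @export
curveSpec <- function(stiffnessNPerMm = 100, yieldLoadN = 40,
                      ultimateLoadN = 60,
                      postYieldStiffnessFraction = 0.2,
                      failureDropFraction = 0.5,
                      displacementRateMmPerMin = 0.1,
                      sampleIntervalS = 10, noiseSdN = 0, seed = 1L) {
  new("CurveSpec", stiffnessNPerMm = as.numeric(stiffnessNPerMm),
      yieldLoadN = as.numeric(yieldLoadN),
      ultimateLoadN = as.numeric(ultimateLoadN),
      postYieldStiffnessFraction = as.numeric(postYieldStiffnessFraction),
      failureDropFraction = as.numeric(failureDropFraction),
      displacementRateMmPerMin = as.numeric(displacementRateMmPerMin),
      sampleIntervalS = as.numeric(sampleIntervalS),
      noiseSdN = as.numeric(noiseSdN), seed = as.integer(seed))
}

#' Specify a synthetic paired treated/control cohort
#'
#' @param nPairs number of animal pairs (default 3, the per-timepoint
#'   group size that reached mechanical testing).
#' @param controlMean mean control-bone property value.
#' @param controlCv coefficient of variation across animals.
#' @param treatmentEffect multiplicative effect (-0.16 = 16% lower).
#' @param pairNoiseCv coefficient of variation of pairwise noise.
#' @param seed RNG seed.
#' @return a [PairedCohortSpec-class].
#' @export
pairedCohortSpec <- function(nPairs = 3L, controlMean = 100,
                             controlCv = 0.1, treatmentEffect = 0,
                             pairNoiseCv = 0.05, seed = 1L) {
  new("PairedCohortSpec", nPairs = as.integer(nPairs),
      controlMean = as.numeric(controlMean),
      controlCv = as.numeric(controlCv),
      treatmentEffect = as.numeric(treatmentEffect),
      pairNoiseCv = as.numeric(pairNoiseCv), seed = as.integer(seed))
}
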