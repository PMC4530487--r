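#' @import methods
NULL

.isCount <- function(x) length(x) == 1L && is.finite(x) && x > 0
.isScalar <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' VoxelImage: a 3D grayscale volume with physical voxel size
#'
#' The carrier for micro-CT-like data.  By convention axis 1 of the grid is
#' the bone shaft / roller-span direction and axis 3 is the vertical load
#' direction.  Intensities live in `[0, dataRangeMax]`, where
#' `dataRangeMax` is the maximum representable value of the storage format
#' (32767 for the signed 16-bit scanner range used by default), not the
#' observed maximum.
#'
#' @slot grid 3D numeric array of intensities.
#' @slot voxelSizeUm isotropic voxel spacing in micrometres.
#' @slot dataRangeMax maximum representable intensity.
#' @slot originMm physical coordinate (mm) of the low corner of voxel
#'   `[1,1,1]` along each axis; tracks crops so that roller positions keep
#'   their meaning.
#' @exportClass VoxelImage
setClass("VoxelImage",
  representation(grid = "array", voxelSizeUm = "numeric",
                 dataRangeMax = "numeric", originMm = "numeric"),
  prototype(voxelSizeUm = 25, dataRangeMax = 32767, originMm = c(0, 0, 0)))

setValidity("VoxelImage", function(object) {
  g <- object@grid
  if (length(dim(g)) != 3L || length(g) == 0L)
    return("grid must be a non-empty 3D array")
  if (!.isCount(object@voxelSizeUm))
    return("voxelSizeUm must be a single positive number")
  if (!.isCount(object@dataRangeMax))
    return("dataRangeMax must be a single positive number")
  if (length(object@originMm) != 3L)
    return("originMm must have length 3")
  rng <- range(g)
  if (rng[1] < -1e-9 * object@dataRangeMax ||
      rng[2] > (1 + 1e-9) * object@dataRangeMax)
    return("intensities must lie within [0, dataRangeMax]")
  TRUE
})

#' BoneMask: a binary 3D grid of mineralized-bone voxels
#'
#' @slot grid 3D logical array; TRUE marks bone.
#' @slot voxelSizeUm isotropic voxel spacing in micrometres.
#' @slot originMm physical coordinate (mm) of the low corner of voxel
#'   `[1,1,1]`.
#' @exportClass BoneMask
setClass("BoneMask",
  representation(grid = "array", voxelSizeUm = "numeric",
                 originMm = "numeric"),
  prototype(voxelSizeUm = 50, originMm = c(0, 0, 0)))

setValidity("BoneMask", function(object) {
  g <- object@grid
  if (length(dim(g)) != 3L) return("grid must be a 3D array")
  if (!is.logical(g)) return("grid must be logical")
  if (!any(g)) return("mask contains no bone voxels")
  if (!.isCount(object@voxelSizeUm))
    return("voxelSizeUm must be a single positive number")
  if (length(object@originMm) != 3L) return("originMm must have length 3")
  TRUE
})

#' SpanCrop: the three-point-bending span geometry
#'
#' Positions are physical coordinates (mm) along axis 1 in the frame of the
#' uncropped volume.
#'
#' @slot rollerPositionsMm the two bottom-roller support coordinates.
#' @slot marginMm extension beyond the rollers on each side (default 0.5).
#' @slot loadPositionMm top-roller coordinate; defaults to the midpoint.
#' @exportClass SpanCrop
setClass("SpanCrop",
  representation(rollerPositionsMm = "numeric", marginMm = "numeric",
                 loadPositionMm = "numeric"))

setValidity("SpanCrop", function(object) {
  r <- object@rollerPositionsMm
  if (length(r) != 2L || !all(is.finite(r)))
    return("rollerPositionsMm must be two finite numbers")
  if (r[1] == r[2]) return("roller positions must be distinct")
  if (!.isScalar(object@marginMm) || object@marginMm < 0)
    return("marginMm must be a single non-negative number")
  lp <- object@loadPositionMm
  if (!.isScalar(lp)) return("loadPositionMm must be a single number")
  if (lp <= min(r) || lp >= max(r))
    return("loadPositionMm must lie strictly between the rollers")
  TRUE
})

#' Material: isotropic linear-elastic tissue properties
#'
#' @slot youngsModulusGPa tissue-level Young's modulus E in GPa (default 10).
#' @slot poissonRatio Poisson's ratio (default 0.3).
#' @exportClass Material
setClass("Material",
  representation(youngsModulusGPa = "numeric", poissonRatio = "numeric"),
  prototype(youngsModulusGPa = 10, poissonRatio = 0.3))

setValidity("Material", function(object) {
  if (!.isCount(object@youngsModulusGPa))
    return("youngsModulusGPa must be positive")
  nu <- object@poissonRatio
  if (!.isScalar(nu) || nu <= -1 || nu >= 0.5)
    return("poissonRatio must lie in (-1, 0.5)")
  TRUE
})

#' BCSet: three-point-bending boundary conditions on a voxel mesh
#'
#' Node ids refer to the owning FEModel's node numbering.  The two support
#' sets have their vertical freedom fixed (rolling-pin idealization); the
#' stabilizers remove the remaining rigid-body motions (axis-1 freedom fixed
#' on set A, axis-2 freedom fixed on one node of set A); the load set gets a
#' prescribed vertical displacement.
#'
#' @slot supportNodesA,supportNodesB node sets at the two bottom rollers.
#' @slot stabilizerNodes node(s) carrying the transverse stabilizing
#'   constraint.
#' @slot loadNodes top-surface node set under the loading roller.
#' @slot prescribedDisplacementMm vertical displacement at the load nodes
#'   (default -0.01 mm).
#' @exportClass BCSet
setClass("BCSet",
  representation(supportNodesA = "integer", supportNodesB = "integer",
                 stabilizerNodes = "integer", loadNodes = "integer",
                 prescribedDisplacementMm = "numeric"),
  prototype(prescribedDisplacementMm = -0.01))

setValidity("BCSet", function(object) {
  if (length(object@supportNodesA) == 0L) return("supportNodesA is empty")
  if (length(object@supportNodesB) == 0L) return("supportNodesB is empty")
  if (length(object@loadNodes) == 0L) return("loadNodes is empty")
  if (length(object@stabilizerNodes) == 0L)
    return("stabilizerNodes is empty")
  d <- object@prescribedDisplacementMm
  if (!.isScalar(d) || d == 0)
    return("prescribedDisplacementMm must be a nonzero number")
  sup <- c(object@supportNodesA, object@supportNodesB)
  if (length(intersect(sup, object@loadNodes)) > 0L)
    return("load nodes must be disjoint from support nodes")
  TRUE
})

#' FEModel: a voxel-conversion hexahedral finite-element model
#'
#' Every bone voxel becomes one 8-node cube element; nodes are the distinct
#' voxel corners on the lattice, each carrying three translational freedoms.
#'
#' @slot mask the source [BoneMask-class].
#' @slot elementSizeUm cube edge length (equals the mask voxel size).
#' @slot material the [Material-class].
#' @slot connectivity integer matrix, 8 x nElements, 1-based node ids in
#'   standard hexahedron corner order.
#' @slot nodeLattice integer matrix, nNodes x 3, 0-based lattice coordinates
#'   of each node (voxel-corner indices).
#' @slot bc the [BCSet-class].
#' @exportClass FEModel
setClass("FEModel",
  representation(mask = "BoneMask", elementSizeUm = "numeric",
                 material = "Material", connectivity = "matrix",
                 nodeLattice = "matrix", bc = "BCSet"))

setValidity("FEModel", function(object) {
  if (nrow(object@connectivity) != 8L)
    return("connectivity must have 8 rows (hex8 elements)")
  nn <- nrow(object@nodeLattice)
  if (ncol(object@nodeLattice) != 3L)
    return("nodeLattice must have 3 columns")
  rng <- range(object@connectivity)
  if (rng[1] < 1L || rng[2] > nn)
    return("connectivity refers to nodes outside the node table")
  ids <- c(object@bc@supportNodesA, object@bc@supportNodesB,
           object@bc@loadNodes, object@bc@stabilizerNodes)
  if (any(ids < 1L) || any(ids > nn))
    return("boundary-condition node ids outside the node table")
  TRUE
})

#' FESolution: displacements and reaction-derived bending stiffness
#'
#' @slot displacements numeric matrix, nNodes x 3, in mm.
#' @slot reactionForceN summed vertical reaction at the load nodes (N).
#' @slot feStiffnessNPerMm |reaction| / |prescribed displacement|.
#' @slot iterations solver iterations used.
#' @slot residual final relative residual.
#' @slot converged logical.
#' @exportClass FESolution
setClass("FESolution",
  representation(displacements = "matrix", reactionForceN = "numeric",
                 feStiffnessNPerMm = "numeric", iterations = "numeric",
                 residual = "numeric", converged = "logical"))

setValidity("FESolution", function(object) {
  if (!.isCount(object@feStiffnessNPerMm))
    return("feStiffnessNPerMm must be positive")
  TRUE
})

#' LoadDisplCurve: a sampled destructive bending test record
#'
#' @slot displacementMm monotone non-decreasing displacement samples
#'   starting at 0.
#' @slot forceN force samples (N), same length.
#' @slot metadata list: specimen id, side (treated/control), timepoint, ...
#' @exportClass LoadDisplCurve
setClass("LoadDisplCurve",
  representation(displacementMm = "numeric", forceN = "numeric",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("LoadDisplCurve", function(object) {
  d <- object@displacementMm
  f <- object@forceN
  if (length(d) != length(f))
    return("displacement and force must have equal length")
  if (length(d) < 20L) return("curve must have at least 20 samples")
  if (abs(d[1]) > 1e-12) return("displacement must start at 0")
  if (any(diff(d) < -1e-12))
    return("displacement must be monotone non-decreasing")
  TRUE
})

#' MechSummary: elastic stiffness, yield load and ultimate load of one test
#'
#' @slot elasticStiffnessNPerMm slope of the detected linear elastic range.
#' @slot yieldLoadN force at the elastic-to-plastic changing point.
#' @slot ultimateLoadN maximum sustained force.
#' @slot fitWindow integer range (first, last sample index) of the elastic
#'   fit.
#' @slot fitR2 coefficient of determination of the elastic fit.
#' @slot flags character vector of quality flags ("low_r2",
#'   "yield_at_ultimate", ...).
#' @slot metadata carried over from the curve.
#' @exportClass MechSummary
setClass("MechSummary",
  representation(elasticStiffnessNPerMm = "numeric", yieldLoadN = "numeric",
                 ultimateLoadN = "numeric", fitWindow = "integer",
                 fitR2 = "numeric", flags = "character", metadata = "list"),
  prototype(flags = character(), metadata = list()))

setValidity("MechSummary", function(object) {
  if (!.isCount(object@elasticStiffnessNPerMm))
    return("elasticStiffnessNPerMm must be positive")
  if (object@yieldLoadN > object@ultimateLoadN * (1 + 1e-9))
    return("yieldLoadN cannot exceed ultimateLoadN")
  r2 <- object@fitR2
  if (!.isScalar(r2) || r2 < -1e-9 || r2 > 1 + 1e-9)
    return("fitR2 must lie in [0, 1]")
  TRUE
})

#' TissueModulusResult: back-calculated bone tissue Young's modulus
#'
#' @slot kExpNPerMm experimentally determined bending stiffness.
#' @slot kFeNPerMm micro-FE-calculated bending stiffness.
#' @slot eRefGpa reference tissue modulus prescribed in the FE model.
#' @slot eTissueGpa `(kExp / kFe) * eRef`.
#' @exportClass TissueModulusResult
setClass("TissueModulusResult",
  representation(kExpNPerMm = "numeric", kFeNPerMm = "numeric",
                 eRefGpa = "numeric", eTissueGpa = "numeric"))

setValidity("TissueModulusResult", function(object) {
  for (s in c("kExpNPerMm", "kFeNPerMm", "eRefGpa", "eTissueGpa"))
    if (!.isCount(slot(object, s))) return(paste(s, "must be positive"))
  ratio <- object@kExpNPerMm / object@kFeNPerMm
  if (object@eTissueGpa != ratio * object@eRefGpa)
    return("eTissueGpa must equal (kExp/kFe) * eRef exactly")
  TRUE
})

#' PairedComparison: a paired treated-versus-control test result
#'
#' @slot pairs two-column matrix (treated, control).
#' @slot differences treated - control.
#' @slot ratios treated / control.
#' @slot test list with elements statistic, z, p.value, method.
#' @exportClass PairedComparison
setClass("PairedComparison",
  representation(pairs = "matrix", differences = "numeric",
                 ratios = "numeric", test = "list"))

setValidity("PairedComparison", function(object) {
  if (ncol(object@pairs) != 2L) return("pairs must have two columns")
  if (nrow(object@pairs) < 1L) return("need at least one pair")
  p <- object@test$p.value
  if (!is.null(p) && !is.na(p) && (p < 0 || p > 1))
    return("p must lie in [0,1]")
  TRUE
})

# ---- generator specification classes -------------------------------------

#' PhantomSpec: parameters of the synthetic femur mid-shaft phantom
#'
#' The phantom is a hollow cortical cylinder aligned with axis 1, optionally
#' with an endosteal woven-bone shell and periosteal thickening as seen
#' after thermal ablation, rendered into a grayscale volume with
#' partial-volume blur and additive noise.
#'
#' @slot lengthMm shaft length (default 12).
#' @slot outerRadiusMm cortical outer radius (default 2).
#' @slot corticalThicknessMm cortical wall thickness (default 0.6).
#' @slot wovenBoneMm endosteal woven-bone shell thickness (default 0 =
#'   untreated control).
#' @slot periostealThickeningMm periosteal new-bone thickness (default 0).
#' @slot voxelSizeUm scan voxel size (default 25).
#' @slot boneGrayLevel,backgroundGrayLevel intensities as fractions of the
#'   data-range maximum (defaults 0.75 and 0.05).
#' @slot blurSigmaUm Gaussian partial-volume blur sigma in micrometres.
#' @slot noiseSd additive Gaussian noise sd as a fraction of the data range.
#' @slot dataRangeMax maximum representable intensity (default 32767).
#' @slot seed integer RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(lengthMm = "numeric", outerRadiusMm = "numeric",
                 corticalThicknessMm = "numeric", wovenBoneMm = "numeric",
                 periostealThickeningMm = "numeric", voxelSizeUm = "numeric",
                 boneGrayLevel = "numeric", backgroundGrayLevel = "numeric",
                 blurSigmaUm = "numeric", noiseSd = "numeric",
                 dataRangeMax = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  for (s in c("lengthMm", "outerRadiusMm", "corticalThicknessMm",
              "voxelSizeUm", "dataRangeMax"))
    if (!.isCount(slot(object, s))) return(paste(s, "must be positive"))
  for (s in c("wovenBoneMm", "periostealThickeningMm", "blurSigmaUm",
              "noiseSd"))
    if (!.isScalar(slot(object, s)) || slot(object, s) < 0)
      return(paste(s, "must be non-negative"))
  if (object@corticalThicknessMm >= object@outerRadiusMm)
    return("corticalThicknessMm must be smaller than outerRadiusMm")
  if (object@wovenBoneMm >
      object@outerRadiusMm - object@corticalThicknessMm)
    return("wovenBoneMm exceeds the medullary radius")
  for (s in c("boneGrayLevel", "backgroundGrayLevel")) {
    v <- slot(object, s)
    if (!.isScalar(v) || v < 0 || v > 1)
      return(paste(s, "must lie in [0, 1]"))
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' CurveSpec: parameters of the synthetic load-displacement curve
#'
#' Bilinear elastic/plastic curve with a terminal failure drop, sampled at
#' the displacement step implied by the crosshead speed and sampling
#' interval, with additive Gaussian force noise.
#'
#' @slot stiffnessNPerMm true elastic stiffness.
#' @slot yieldLoadN,ultimateLoadN true yield and ultimate loads.
#' @slot postYieldStiffnessFraction plastic slope as a fraction of the
#'   elastic slope (default 0.2).
#' @slot failureDropFraction force retained after failure as a fraction of
#'   the ultimate load (default 0.5).
#' @slot displacementRateMmPerMin crosshead speed (default 0.1).
#' @slot sampleIntervalS sampling interval (default 10).
#' @slot noiseSdN additive force noise sd (N).
#' @slot seed integer RNG seed.
#' @exportClass CurveSpec
setClass("CurveSpec",
  representation(stiffnessNPerMm = "numeric", yieldLoadN = "numeric",
                 ultimateLoadN = "numeric",
                 postYieldStiffnessFraction = "numeric",
                 failureDropFraction = "numeric",
                 displacementRateMmPerMin = "numeric",
                 sampleIntervalS = "numeric", noiseSdN = "numeric",
                 seed = "integer"))

setValidity("CurveSpec", function(object) {
  for (s in c("stiffnessNPerMm", "yieldLoadN", "ultimateLoadN",
              "displacementRateMmPerMin", "sampleIntervalS"))
    if (!.isCount(slot(object, s))) return(paste(s, "must be positive"))
  if (!(object@yieldLoadN < object@ultimateLoadN))
    return("yieldLoadN must be smaller than ultimateLoadN")
  p <- object@postYieldStiffnessFraction
  if (!.isScalar(p) || p < 0 || p >= 1)
    return("postYieldStiffnessFraction must lie in [0, 1)")
  fr <- object@failureDropFraction
  if (!.isScalar(fr) || fr < 0 || fr > 1)
    return("failureDropFraction must lie in [0, 1]")
  if (!.isScalar(object@noiseSdN) || object@noiseSdN < 0)
    return("noiseSdN must be non-negative")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' PairedCohortSpec: parameters of a synthetic paired animal cohort
#'
#' Control-bone property values are i.i.d. lognormal; the treated side is
#' the control times a multiplicative treatment effect with lognormal pair
#' noise.
#'
#' @slot nPairs number of animal pairs (default 3, the per-timepoint
#'   mechanics group size).
#' @slot controlMean,controlCv mean and coefficient of variation of the
#'   control-bone property.
#' @slot treatmentEffect multiplicative effect, e.g. -0.16 for 16% lower.
#' @slot pairNoiseCv coefficient of variation of the pairwise noise.
#' @slot seed integer RNG seed.
#' @exportClass PairedCohortSpec
setClass("PairedCohortSpec",
  representation(nPairs = "integer", controlMean = "numeric",
                 controlCv = "numeric", treatmentEffect = "numeric",
                 pairNoiseCv = "numeric", seed = "integer"))

setValidity("PairedCohortSpec", function(object) {
  if (length(object@nPairs) != 1L || is.na(object@nPairs) ||
      object@nPairs < 1L)
    return("nPairs must be a positive integer")
  if (!.isCount(object@controlMean)) return("controlMean must be positive")
  for (s in c("controlCv", "pairNoiseCv"))
    if (!.isScalar(slot(object, s)) || slot(object, s) < 0)
      return(paste(s, "must be non-negative"))
  if (!.isScalar(object@treatmentEffect) || object@treatmentEffect <= -1)
    return("treatmentEffect must be greater than -1")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})
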