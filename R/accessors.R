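#' @include AllClasses.R AllGenerics.R
NULL

#' Voxel spacing accessor
#'
#' @param object a [VoxelImage-class], [BoneMask-class] or
#'   [FEModel-class].
#' @return voxel (element) spacing in micrometres.
#' @name voxelSize
NULL

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VoxelImage", function(object) object@voxelSizeUm)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "BoneMask", function(object) object@voxelSizeUm)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "FEModel", function(object) object@elementSizeUm)

#' Intensity array accessor
#'
#' @param object a [VoxelImage-class].
#' @return the 3D intensity array.
#' @name intensities
NULL

#' @rdname intensities
#' @export
setMethod("intensities", "VoxelImage", function(object) object@grid)

#' Mask array accessor
#'
#' @param object a [BoneMask-class] or [FEModel-class].
#' @return the 3D logical array.
#' @name maskArray
NULL

#' @rdname maskArray
#' @export
setMethod("maskArray", "BoneMask", function(object) object@grid)
#' @rdname maskArray
#' @export
setMethod("maskArray", "FEModel", function(object) object@mask@grid)

#' FE bending stiffness accessor
#'
#' @param object an [FESolution-class].
#' @return stiffness in N/mm.
#' @name feStiffness
NULL

#' @rdname feStiffness
#' @export
setMethod("feStiffness", "FESolution",
          function(object) object@feStiffnessNPerMm)

#' Nodal displacement accessor
#'
#' @param object an [FESolution-class].
#' @return numeric matrix nNodes x 3 (mm).
#' @name displacements
NULL

#' @rdname displacements
#' @export
setMethod("displacements", "FESolution",
          function(object) object@displacements)

#' Back-calculated tissue modulus accessor
#'
#' @param object a [TissueModulusResult-class].
#' @return tissue Young's modulus in GPa.
#' @name tissueModulus
NULL

#' @rdname tissueModulus
#' @export
setMethod("tissueModulus", "TissueModulusResult",
          function(object) object@eTissueGpa)

#' @export
setMethod("elasticStiffness", "MechSummary",
          function(object, ...) object@elasticStiffnessNPerMm)
#' @export
setMethod("ultimateLoad", "MechSummary",
          function(object, ...) object@ultimateLoadN)
#' @export
setMethod("yieldLoad", "MechSummary",
          function(object, ...) object@yieldLoadN)

#' @export
setMethod("dim", "VoxelImage", function(x) dim(x@grid))
#' @export
setMethod("dim", "BoneMask", function(x) dim(x@grid))

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@grid)
  cat(sprintf("VoxelImage: %d x %d x %d voxels at %g um\n",
              d[1], d[2], d[3], object@voxelSizeUm))
  cat(sprintf("  intensity range [%.1f, %.1f] of max %g\n",
              min(object@grid), max(object@grid), object@dataRangeMax))
  cat(sprintf("  origin (mm): %g, %g, %g\n", object@originMm[1],
              object@originMm[2], object@originMm[3]))
})

setMethod("show", "BoneMask", function(object) {
  d <- dim(object@grid)
  cat(sprintf("BoneMask: %d x %d x %d voxels at %g um, %d bone voxels\n",
              d[1], d[2], d[3], object@voxelSizeUm, sum(object@grid)))
})

setMethod("show", "FEModel", function(object) {
  cat(sprintf("FEModel: %d hex8 elements, %d nodes, edge %g um\n",
              ncol(object@connectivity), nrow(object@nodeLattice),
              object@elementSizeUm))
  cat(sprintf("  material: E = %g GPa, nu = %g\n",
              object@material@youngsModulusGPa,
              object@material@poissonRatio))
  cat(sprintf(
    "  bc: %d + %d support nodes, %d load nodes, delta = %g mm\n",
    length(object@bc@supportNodesA), length(object@bc@supportNodesB),
    length(object@bc@loadNodes), object@bc@prescribedDisplacementMm))
})

setMethod("show", "FESolution", function(object) {
  cat(sprintf(
    "FESolution: stiffness %.4g N/mm (reaction %.4g N), %d iterations,\n",
    object@feStiffnessNPerMm, object@reactionForceN,
    as.integer(object@iterations)))
  cat(sprintf("  relative residual %.3g (converged: %s)\n",
              object@residual, object@converged))
})

setMethod("show", "LoadDisplCurve", function(object) {
  cat(sprintf(
    "LoadDisplCurve: %d samples, displacement 0..%.3g mm, max force %.4g N\n",
    length(object@forceN), max(object@displacementMm),
    max(object@forceN)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata),
        vapply(object@metadata, format, ""), sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "MechSummary", function(object) {
  cat(sprintf(
    "MechSummary: stiffness %.4g N/mm, yield %.4g N, ultimate %.4g N\n",
    object@elasticStiffnessNPerMm, object@yieldLoadN, object@ultimateLoadN))
  cat(sprintf("  elastic fit: samples %d..%d, R2 = %.5f%s\n",
              object@fitWindow[1], object@fitWindow[2], object@fitR2,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ", "), "]")
              else ""))
})

setMethod("show", "TissueModulusResult", function(object) {
  cat(sprintf(
    "TissueModulusResult: E_tissue = %.4g GPa (k_exp %.4g / k_fe %.4g x %g)\n",
    object@eTissueGpa, object@kExpNPerMm, object@kFeNPerMm,
    object@eRefGpa))
})

setMethod("show", "PairedComparison", function(object) {
  cat(sprintf("PairedComparison: n = %d pairs, %s\n", nrow(object@pairs),
              object@test$method))
  cat(sprintf("  mean ratio %.3f, statistic %.3g, p = %.4g\n",
              mean(object@ratios), object@test$statistic,
              object@test$p.value))
})
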