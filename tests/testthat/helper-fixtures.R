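# Shared fixtures: all built in code at test time.

# Solid square-section beam mask (edge x edge x length), axis 1 = span.
beamMask <- function(voxelUm, lengthMm = 10.6, edgeMm = 1.2) {
  h <- voxelUm / 1000
  boneMask(array(TRUE, c(round(lengthMm / h), round(edgeMm / h),
                         round(edgeMm / h))), voxelUm)
}

# The beam bending setup used across FE tests: 9.6 mm span, load midspan.
beamCrop <- function() spanCrop(c(0.5, 10.1), marginMm = 0.25)

# Small noiseless hollow-cylinder phantom spec.
cleanCylinderSpec <- function(voxelUm = 100, lengthMm = 6,
                              outerRadiusMm = 1.0,
                              corticalThicknessMm = 0.35, ...) {
  phantomSpec(lengthMm = lengthMm, outerRadiusMm = outerRadiusMm,
              corticalThicknessMm = corticalThicknessMm,
              voxelSizeUm = voxelUm, blurSigmaUm = 0, noiseSd = 0, ...)
}

# Random connected voxel blob of at most maxElements elements.
randomBlobMask <- function(seed, dim = c(6, 6, 6), p = 0.65,
                           voxelUm = 500) {
  withr::with_seed(seed, {
    g <- array(runif(prod(dim)) < p, dim)
    g[, , 1] <- TRUE  # guarantee a bottom layer so rollers can touch
    m <- largestComponent(boneMask(g, voxelUm))
    m
  })
}

# Displacement step (mm) implied by a CurveSpec's speed and interval.
curveStep <- function(spec) {
  spec@displacementRateMmPerMin / 60 * spec@sampleIntervalS
}
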