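test_that("noiseless phantom reproduces the analytic annulus voxel-for-voxel", {
  spec <- phantomSpec(blurSigmaUm = 0, noiseSd = 0)  # 2 mm / 0.6 mm / 25 um
  img <- generateFemurPhantom(spec)
  g <- intensities(img)
  d <- dim(g)
  h <- voxelSize(img) / 1000
  ctr <- d[2] * h / 2
  yc <- (seq_len(d[2]) - 0.5) * h - ctr
  zc <- (seq_len(d[3]) - 0.5) * h - ctr
  r <- sqrt(outer(yc^2, zc^2, "+"))
  inside <- r >= 1.4 & r < 2.0          # voxel-center membership rule
  expected <- ifelse(inside, 0.75, 0.05) * 32767
  for (slice in c(1L, d[1] %/% 2, d[1]))
    expect_equal(g[slice, , ], expected)

  # analytic area vs voxel count, per slice
  area <- sum(inside) * h^2
  expect_lt(abs(area / (pi * (2^2 - 1.4^2)) - 1), 0.02)

  # mask after the standard threshold equals the exact annulus
  mask <- thresholdPermille(img, 500)
  expect_identical(maskArray(mask)[d[1] %/% 2, , ], inside)
})

test_that("phantom generation is a pure function of its spec", {
  spec <- phantomSpec(lengthMm = 2, outerRadiusMm = 1,
                      corticalThicknessMm = 0.3, voxelSizeUm = 100,
                      blurSigmaUm = 50, noiseSd = 0.05, seed = 7L)
  a <- generateFemurPhantom(spec)
  b <- generateFemurPhantom(spec)
  expect_identical(intensities(a), intensities(b))
  c2 <- generateFemurPhantom(phantomSpec(lengthMm = 2, outerRadiusMm = 1,
                                         corticalThicknessMm = 0.3,
                                         voxelSizeUm = 100,
                                         blurSigmaUm = 50, noiseSd = 0.05,
                                         seed = 8L))
  expect_false(identical(intensities(a), intensities(c2)))
  # RNG state of the session is not consumed
  withr::with_seed(1, {
    before <- .Random.seed
    generateFemurPhantom(spec)
    expect_identical(before, .Random.seed)
  })
})

test_that("impossible phantom geometry is rejected with the offending dimension", {
  expect_error(phantomSpec(wovenBoneMm = 2), "wovenBoneMm")
  expect_error(phantomSpec(corticalThicknessMm = 3), "corticalThicknessMm")
  expect_error(phantomSpec(outerRadiusMm = -1), "outerRadiusMm")
})

test_that("treated-phantom shells appear at the expected radii", {
  base <- cleanCylinderSpec(voxelUm = 50, outerRadiusMm = 1.2,
                            corticalThicknessMm = 0.4)
  treated <- cleanCylinderSpec(voxelUm = 50, outerRadiusMm = 1.2,
                               corticalThicknessMm = 0.4,
                               wovenBoneMm = 0.2,
                               periostealThickeningMm = 0.15)
  nCtl <- sum(thresholdPermille(generateFemurPhantom(base)) |> maskArray())
  nTrt <- sum(thresholdPermille(generateFemurPhantom(treated)) |>
                maskArray())
  # mineralized area grows by the two shells
  h <- 0.05
  aCtl <- pi * (1.2^2 - 0.8^2)
  aTrt <- pi * (1.35^2 - 0.6^2)
  expect_equal(nTrt / nCtl, aTrt / aCtl, tolerance = 0.03)
})

test_that("noiseless curve is exactly bilinear and analyzable in closed form", {
  spec <- curveSpec(stiffnessNPerMm = 100, yieldLoadN = 40,
                    ultimateLoadN = 60)
  crv <- generateLoadCurve(spec)
  d <- displacementSamples(crv)
  f <- forceSamples(crv)
  expect_equal(d[1], 0)
  i02 <- which(abs(d - 0.2) < 1e-12)
  expect_length(i02, 1L)
  expect_equal(f[i02], 20)              # linear segment: k * d
  expect_true(all(diff(d) > 0))
  # round trip through the analyzer (mutual-oracle property)
  s <- analyzeCurve(crv)
  step <- curveStep(spec)
  expect_equal(elasticStiffness(s), 100, tolerance = 1e-12)
  expect_equal(s@fitR2, 1, tolerance = 1e-9)
  expect_lt(abs(ultimateLoad(s) - 60), 0.2 * 100 * step + 1e-9)
  expect_lt(abs(yieldLoad(s) - 40), 100 * step + 1e-9)
})

test_that("curve generation is deterministic and respects invariants", {
  spec <- curveSpec(noiseSdN = 0.5, seed = 3L)
  a <- generateLoadCurve(spec)
  b <- generateLoadCurve(spec)
  expect_identical(forceSamples(a), forceSamples(b))
  expect_error(curveSpec(yieldLoadN = 70, ultimateLoadN = 60),
               "yieldLoadN")
  expect_error(curveSpec(postYieldStiffnessFraction = 1),
               "postYieldStiffnessFraction")
})

test_that("noisy curves still recover the true stiffness", {
  ks <- vapply(1:25, function(sd) {
    crv <- generateLoadCurve(curveSpec(stiffnessNPerMm = 100,
                                       yieldLoadN = 40, ultimateLoadN = 60,
                                       noiseSdN = 0.5, seed = sd))
    elasticStiffness(analyzeCurve(crv))
  }, 0)
  expect_true(all(abs(ks / 100 - 1) < 0.05))
})

test_that("paired cohort generator has the prescribed structure", {
  pure <- generatePairedCohort(pairedCohortSpec(treatmentEffect = 0,
                                                pairNoiseCv = 0))
  expect_equal(pure$treated, pure$control)
  eff <- generatePairedCohort(pairedCohortSpec(treatmentEffect = -0.16,
                                               pairNoiseCv = 0))
  expect_equal(eff$treated / eff$control, rep(0.84, 3))
  # strong effect: essentially every cohort has all-one-sign differences
  shares <- vapply(1:300, function(sd) {
    ch <- generatePairedCohort(pairedCohortSpec(treatmentEffect = -0.3,
                                                seed = sd))
    all(ch$treated < ch$control)
  }, TRUE)
  expect_gte(mean(shares), 0.99)
  # lognormal control scale sanity over many draws
  big <- generatePairedCohort(pairedCohortSpec(nPairs = 2000L,
                                               controlMean = 100,
                                               controlCv = 0.1, seed = 11L))
  expect_equal(mean(big$control), 100, tolerance = 0.02)
  expect_equal(sd(big$control) / mean(big$control), 0.1, tolerance = 0.1)
})
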