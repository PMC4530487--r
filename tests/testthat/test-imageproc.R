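test_that("MetaImage and NIfTI volumes round-trip exactly", {
  withr::with_seed(42, {
    g <- array(round(runif(1000, 0, 32767)), c(10, 10, 10))
  })
  img <- voxelImage(g, 25)
  for (ext in c("vol.mha", "vol.nii.gz")) {
    path <- file.path(withr::local_tempdir(), ext)
    writeVolume(img, path)
    back <- readVolume(path)
    expect_equal(intensities(back), g, ignore_attr = TRUE)
    expect_equal(voxelSize(back), 25)
  }
})

test_that("TIFF stacks need explicit spacing and anisotropy is rejected", {
  tmp <- withr::local_tempdir()
  tf <- file.path(tmp, "stack.tif")
  pages <- lapply(1:4, function(k) matrix(k / 10, 6, 5))
  tiff::writeTIFF(pages, tf, bits.per.sample = 32L)
  expect_error(readVolume(tf), "spacingUm")
  img <- readVolume(tf, spacingUm = 25, dataRangeMax = 1)
  expect_equal(dim(img), c(6L, 5L, 4L))
  expect_equal(intensities(img)[1, 1, 3], 0.3, tolerance = 1e-4)

  nf <- file.path(tmp, "aniso.nii.gz")
  nim <- RNifti::asNifti(array(0, c(4, 4, 4)))
  RNifti::pixdim(nim) <- c(0.025, 0.025, 0.05)
  RNifti::writeNifti(nim, nf)
  expect_error(readVolume(nf), "isotropic")
})

test_that("axis-aligned reorientation is lossless and composes as a group", {
  withr::with_seed(1, g <- array(runif(4 * 5 * 6), c(4, 5, 6)))
  img <- voxelImage(g, 50, dataRangeMax = 1)
  expect_identical(intensities(reorient(img)), g)
  # two quarter-turns about axis 1 == one half-turn (flip axes 2 and 3)
  quarter <- function(x) reorient(x, permutation = c(1L, 3L, 2L),
                                  flip = c(FALSE, FALSE, TRUE))
  twice <- quarter(quarter(img))
  half <- reorient(img, flip = c(FALSE, TRUE, TRUE))
  expect_identical(intensities(twice), intensities(half))
  expect_error(reorient(img, permutation = c(1L, 1L, 2L)), "permutation")
  expect_error(reorient(img, rotationMatrix = matrix(1, 3, 3)),
               "orthonormal")
})

test_that("small-angle rotation round-trips within interpolation tolerance", {
  spec <- cleanCylinderSpec(voxelUm = 100, lengthMm = 3,
                            outerRadiusMm = 0.9)
  img <- generateFemurPhantom(phantomSpec(lengthMm = 3,
                                          outerRadiusMm = 0.9,
                                          corticalThicknessMm = 0.35,
                                          voxelSizeUm = 100,
                                          blurSigmaUm = 300, noiseSd = 0))
  fwd <- reorient(img, anglesDeg = c(10, 0, 0))
  back <- reorient(fwd, anglesDeg = c(-10, 0, 0))
  d <- dim(img)
  core <- list(5:(d[1] - 4), 5:(d[2] - 4), 5:(d[3] - 4))
  delta <- abs(intensities(back)[core[[1]], core[[2]], core[[3]]] -
               intensities(img)[core[[1]], core[[2]], core[[3]]])
  expect_lt(max(delta), 0.02 * img@dataRangeMax)
})

test_that("block-mean downsampling averages, conserves intensity, checks factors", {
  const <- voxelImage(array(7, c(4, 4, 4)), 25)
  expect_true(all(intensities(downsampleTo(const, 50)) == 7))
  blk <- voxelImage(array(0:7 * 3, c(2, 2, 2)), 25, dataRangeMax = 32767)
  expect_equal(as.numeric(intensities(downsampleTo(blk, 50))), 3.5 * 3)
  withr::with_seed(9, g <- array(runif(8 * 6 * 4, 0, 100), c(8, 6, 4)))
  img <- voxelImage(g, 25, dataRangeMax = 100)
  down <- downsampleTo(img, 50)
  expect_equal(sum(intensities(down)) * 8, sum(g))
  expect_equal(voxelSize(down), 50)
  expect_error(downsampleTo(img, 60), "integer multiple")
})

test_that("per-mille threshold cuts at the data-range fraction", {
  g <- array(c(16383, 16384, 0, 32767, rep(0, 4)), c(2, 2, 2))
  img <- voxelImage(g, 50)
  m <- maskArray(thresholdPermille(img, 500))
  expect_false(m[1, 1, 1])   # 16383 < 16383.5
  expect_true(m[2, 1, 1])    # 16384 >= 16383.5
  expect_error(thresholdPermille(img, 0), "permille")
  sat <- maskArray(thresholdPermille(img, 1000))
  expect_equal(which(sat), which(g == 32767))
  # observed-maximum reference
  half <- voxelImage(array(c(50, 100, rep(0, 6)), c(2, 2, 2)), 50,
                     dataRangeMax = 32767)
  expect_equal(sum(maskArray(thresholdPermille(half, 500, "observed"))),
               2L)
  # monotonicity: raising the threshold never adds voxels
  withr::with_seed(5, gg <- array(runif(512, 0, 32767), c(8, 8, 8)))
  imgg <- voxelImage(gg, 50)
  n <- vapply(c(100, 300, 500, 700, 900),
              function(p) sum(maskArray(thresholdPermille(imgg, p))), 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("span crop uses half-open voxel windows and is idempotent", {
  g <- array(FALSE, c(240, 4, 4)); g[, 2:3, 2:3] <- TRUE
  mask <- boneMask(g, 50)
  crop <- spanCrop(c(1, 11), marginMm = 0.5)
  out <- cropToSpan(mask, crop)
  expect_equal(dim(maskArray(out))[1], 220L)   # indices [10, 230)
  expect_equal(out@originMm[1], 0.5)
  again <- cropToSpan(out, crop)
  expect_identical(maskArray(again), maskArray(out))
  tight <- cropToSpan(mask, spanCrop(c(1, 11), marginMm = 0))
  expect_equal(dim(maskArray(tight))[1], 200L)  # [20, 220)
  expect_equal(tight@originMm[1], 1.0)
  expect_error(spanCrop(c(5, 5)), "distinct")
  expect_error(spanCrop(c(1, 11), loadPositionMm = 12), "between")
})

test_that("largest-component cleanup keeps one component with the tie rule", {
  spec <- cleanCylinderSpec(voxelUm = 100, lengthMm = 2)
  mask <- thresholdPermille(generateFemurPhantom(spec))
  expect_identical(maskArray(largestComponent(mask)), maskArray(mask))
  withSpeck <- maskArray(mask)
  withSpeck[1, 1, 1] <- TRUE            # isolated corner speck
  cleaned <- largestComponent(boneMask(withSpeck, 100))
  expect_identical(maskArray(cleaned), maskArray(mask))
  # two equal components: keep the one with the smallest linear index
  g <- array(FALSE, c(6, 3, 3))
  g[1:2, 1, 1] <- TRUE
  g[5:6, 3, 3] <- TRUE
  kept <- maskArray(largestComponent(boneMask(g, 100)))
  expect_true(all(kept[1:2, 1, 1]))
  expect_false(any(kept[5:6, 3, 3]))
})

test_that("the preprocessing chain composes in the fixed order", {
  spec <- phantomSpec(lengthMm = 4, outerRadiusMm = 1,
                      corticalThicknessMm = 0.35, voxelSizeUm = 50,
                      blurSigmaUm = 25, noiseSd = 0.01, seed = 2L)
  img <- generateFemurPhantom(spec)
  crop <- spanCrop(c(0.5, 3.5), marginMm = 0.25)
  mask <- preprocessVolume(img, crop, targetUm = 100)
  expect_s4_class(mask, "BoneMask")
  expect_equal(voxelSize(mask), 100)
  expect_equal(dim(maskArray(mask))[1], 36L)  # [0.25, 3.75) mm at 0.1 mm
  expect_gt(sum(maskArray(mask)), 0)
})
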