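test_that("tissue-modulus back-calculation is the exact stiffness ratio", {
  expect_equal(tissueModulus(backCalculateTissueModulus(100, 100)), 10)
  expect_equal(tissueModulus(backCalculateTissueModulus(200, 100)), 20)
  # scale equivariance
  a <- tissueModulus(backCalculateTissueModulus(123.4, 98.7))
  b <- tissueModulus(backCalculateTissueModulus(123.4 * 7, 98.7 * 7))
  expect_equal(a, b)
  expect_error(backCalculateTissueModulus(-1, 100), "positive")
  expect_error(backCalculateTissueModulus(100, 0), "positive")
})

test_that("asymptotic signed-rank p at n=3 reproduces the anchor triple", {
  # T = 0: all three differences share one sign
  r0 <- wilcoxonSignedRank(c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$z, -1.6036, tolerance = 1e-4)
  expect_equal(r0$p.value, 0.1088, tolerance = 1e-3)
  expect_equal(round(r0$p.value, 2), 0.11)
  # T = 1: smallest-magnitude difference flips sign
  r1 <- wilcoxonSignedRank(c(-1, 2, 3))
  expect_equal(r1$statistic, 1)
  expect_equal(r1$p.value, 0.2850, tolerance = 1e-3)
  expect_equal(round(r1$p.value, 2), 0.29)
  # T = 2
  r2 <- wilcoxonSignedRank(c(1, -2, 3))
  expect_equal(r2$statistic, 2)
  expect_equal(r2$p.value, 0.5930, tolerance = 1e-3)
  expect_equal(round(r2$p.value, 2), 0.59)
})

test_that("exact signed-rank enumeration matches closed counts and conventions", {
  ex <- wilcoxonSignedRank(c(1, 2, 3), mode = "exact")
  expect_equal(ex$p.value, 0.25)       # 2 * 1/2^3
  # zeros dropped before ranking
  z <- wilcoxonSignedRank(c(0, 1, 2, 3), mode = "exact")
  expect_equal(z$nUsed, 3)
  expect_equal(z$p.value, 0.25)
  expect_error(wilcoxonSignedRank(c(0, 0, 0)), "zero")
  # exact p can never undercut the attainable minimum
  for (n in c(3, 5, 8)) {
    p <- wilcoxonSignedRank(seq_len(n), mode = "exact")$p.value
    expect_gte(p, 2 * (1 / 2^n) - 1e-12)
  }
})

test_that("signed-rank agrees with the reference implementation off the anchor", {
  for (sd in 1:8) {
    d <- withr::with_seed(sd, rnorm(12) + 0.4)
    ours <- wilcoxonSignedRank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE,
                                               correct = FALSE))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    oursEx <- wilcoxonSignedRank(d, mode = "exact")
    refEx <- stats::wilcox.test(d, mu = 0, exact = TRUE)
    expect_equal(oursEx$p.value, refEx$p.value, tolerance = 1e-10)
  }
})

test_that("exact and asymptotic modes converge for larger samples", {
  for (sd in 1:5) {
    d <- withr::with_seed(100 + sd, rnorm(30, mean = 0.2))
    pa <- wilcoxonSignedRank(d)$p.value
    pe <- wilcoxonSignedRank(d, mode = "exact")$p.value
    expect_lt(abs(pa - pe), 0.02)
  }
})

test_that("two-sided t test matches the closed form and handles degeneracy", {
  same <- twoSidedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p.value, 1)
  paired <- twoSidedTTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(paired$t, 0)
  expect_equal(paired$p.value, 1)
  # closed-form pooled-variance oracle: means 12 vs 22, s^2 = 4 each
  tt <- twoSidedTTest(c(10, 12, 14), c(20, 22, 24))
  tOracle <- (12 - 22) / (2 * sqrt(2 / 3))
  expect_equal(tt$t, tOracle, tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p.value, 2 * stats::pt(tOracle, 4), tolerance = 1e-12)
  welch <- twoSidedTTest(c(10, 12, 14), c(20, 22, 30), welch = TRUE)
  expect_match(welch$method, "Welch")
  expect_error(twoSidedTTest(c(1, 1), c(1, 1)), "variance")
  expect_error(twoSidedTTest(c(1, 2, 3), c(2, 3, 4), paired = TRUE),
               "zero variance")
  expect_error(twoSidedTTest(1, c(1, 2)), "two observations")
})

test_that("cohort report computes percent differences and paired tests", {
  mech <- expand.grid(specimen = c("r1", "r2", "r3"),
                      timepoint = c("7d", "1m"),
                      side = c("treated", "control"),
                      stringsAsFactors = FALSE)
  mech$stiffness_n_per_mm <- ifelse(mech$side == "control", 100, 84)
  mech$yield_load_n <- ifelse(mech$side == "control", 40, 40 * 0.84)
  mech$ultimate_load_n <- ifelse(mech$side == "control", 60, 60 * 0.84)
  fe <- mech[, c("specimen", "timepoint", "side")]
  fe$fe_stiffness_n_per_mm <- ifelse(fe$side == "control", 90, 90 * 0.84)
  rep <- cohortReport(mech, fe)
  stiff7 <- subset(rep$perTimepoint,
                   timepoint == "7d" & property == "stiffness_n_per_mm")
  expect_equal(stiff7$mean_pct_diff, -16)     # "16 +/- 0 % less"
  expect_equal(stiff7$sd_pct_diff, 0)
  expect_equal(stiff7$wilcoxon_T, 0)
  # all three differences are exactly equal here, so the tie-corrected
  # variance is n(n+1)(2n+1)/24 - (t^3-t)/48 = 3 and z = -sqrt(3)
  expect_equal(stiff7$p_value, 2 * stats::pnorm(-sqrt(3)),
               tolerance = 1e-9)
  # tissue modulus is stiffness ratio x reference; here both sides scale
  # identically, so the paired test is undefined and reported as NA
  et <- subset(rep$perTimepoint,
               timepoint == "7d" & property == "e_tissue_gpa")
  expect_equal(et$mean_pct_diff, 0, tolerance = 1e-9)
  expect_true(is.na(et$p_value))

  broken <- mech[!(mech$specimen == "r2" & mech$side == "control" &
                   mech$timepoint == "7d"), ]
  expect_error(cohortReport(broken, fe), "r2")
})

test_that("null cohorts never reject at alpha = 0.05 with exact n = 3 inference", {
  ps <- vapply(1:100, function(sd) {
    ch <- generatePairedCohort(pairedCohortSpec(treatmentEffect = 0,
                                                pairNoiseCv = 0.05,
                                                seed = sd))
    wilcoxonSignedRank(ch$treated, ch$control, mode = "exact")$p.value
  }, 0)
  expect_true(all(ps >= 0.25 - 1e-12))
  expect_equal(mean(ps < 0.05), 0)
})
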