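#' @include constructors.R
NULL

#' Back-calculate the bone tissue Young's modulus
#'
#' The micro-FE model is linear in the tissue modulus, so the actual
#' tissue modulus follows from the ratio of the experimentally determined
#' bending stiffness to the FE-calculated stiffness, multiplied by the
#' reference modulus prescribed in the model:
#' `E_tissue = (k_exp / k_fe) * E_ref`.  An exact ratio formula — no
#' fitting — and scale-equivariant: multiplying both stiffnesses by the
#' same factor leaves the result unchanged.
#'
#' @param kExpNPerMm experimental bending stiffness (N/mm).
#' @param kFeNPerMm micro-FE bending stiffness at the reference modulus.
#' @param eRefGpa reference tissue modulus (default 10 GPa).
#' @return a [TissueModulusResult-class].
#' @examples
#' tissueModulus(backCalculateTissueModulus(200, 100))  # 20 GPa
#' @export
backCalculateTissueModulus <- function(kExpNPerMm, kFeNPerMm,
                                       eRefGpa = 10) {
  if (!is.numeric(kExpNPerMm) || kExpNPerMm <= 0 ||
      !is.numeric(kFeNPerMm) || kFeNPerMm <= 0 || eRefGpa <= 0)
    stop("stiffnesses and the reference modulus must be positive")
  ratio <- kExpNPerMm / kFeNPerMm
  new("TissueModulusResult", kExpNPerMm = as.numeric(kExpNPerMm),
      kFeNPerMm = as.numeric(kFeNPerMm), eRefGpa = as.numeric(eRefGpa),
      eTissueGpa = ratio * as.numeric(eRefGpa))
}

# Exact null distribution of the positive rank sum W+ by dynamic
# programming over the 2^n sign patterns.  Average (tied) ranks are
# multiples of 1/2, so doubling makes the support integral.
.wplusDistribution <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  prob <- numeric(total + 1L)  # support 0..total on the doubled scale
  prob[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), prob[seq_len(total + 1L - r)])
    prob <- (prob + shifted) / 2
  }
  prob
}

#' Wilcoxon signed-rank test for paired comparisons
#'
#' The paired test used for all treated-versus-control comparisons.  Zero
#' differences are dropped before ranking and ties receive average ranks
#' (the SPSS convention).  The statistic `T` is the smaller of the
#' positive and negative rank sums.  In asymptotic mode the normal
#' approximation without continuity correction is used,
#' `z = (T - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - tie correction)`, which at
#' n = 3 gives two-sided p = 0.109, 0.285, 0.593 for T = 0, 1, 2.  Exact
#' mode enumerates the full sign-pattern null distribution of the rank sum
#' (two-sided p = twice the smaller tail, capped at 1); at n = 3 and T = 0
#' this gives p = 0.25, the smallest attainable value.
#'
#' @param treated numeric vector: treated-side values, or differences if
#'   `control` is `NULL`.
#' @param control numeric vector of paired control values, or `NULL`.
#' @param mode `"asymptotic"` (default) or `"exact"`.
#' @param twoSided two-sided p (default TRUE).
#' @return list with `statistic` (T), `Wplus`, `Wminus`, `z`, `p.value`,
#'   `nUsed`, `method`.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3))               # all one sign: T = 0
#' wilcoxonSignedRank(c(1, 2, 3), mode = "exact")
#' @export
wilcoxonSignedRank <- function(treated, control = NULL,
                               mode = c("asymptotic", "exact"),
                               twoSided = TRUE) {
  mode <- match.arg(mode)
  d <- if (is.null(control)) as.numeric(treated)
       else as.numeric(treated) - as.numeric(control)
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L)
    stop("all paired differences are zero: the signed-rank test is ",
         "undefined")
  ranks <- rank(abs(d))
  wplus <- sum(ranks[d > 0])
  wminus <- sum(ranks[d < 0])
  Tstat <- min(wplus, wminus)
  if (mode == "asymptotic") {
    mu <- n * (n + 1) / 4
    tieCounts <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tieCounts^3 - tieCounts) / 48
    z <- (Tstat - mu) / sqrt(sigma2)
    p <- if (twoSided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z)
    method <- "Wilcoxon signed-rank (normal approximation, no continuity correction)"
  } else {
    prob <- .wplusDistribution(ranks)
    w2 <- as.integer(round(2 * wplus))
    lower <- sum(prob[seq_len(w2 + 1L)])
    upper <- sum(prob[(w2 + 1L):length(prob)])
    p <- if (twoSided) min(1, 2 * min(lower, upper)) else lower
    z <- NA_real_
    method <- "Wilcoxon signed-rank (exact enumeration)"
  }
  list(statistic = Tstat, Wplus = wplus, Wminus = wminus, z = z,
       p.value = p, nUsed = n, method = method)
}

#' Two-sided t test (pooled-variance default)
#'
#' Used to compare properties across timepoints.  The unpaired test
#' defaults to the pooled-variance Student form (the "equal variances
#' assumed" row); Welch's form is available by flag.  The paired form
#' tests the differences.  Samples with zero variance are rejected, except
#' for the degenerate paired case of identically equal samples, which
#' returns t = 0, p = 1.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param paired paired test on `a - b`.
#' @param welch unpaired only: use Welch's unequal-variance form.
#' @return list with `t`, `df`, `p.value`, `method`.
#' @export
twoSidedTTest <- function(a, b, paired = FALSE, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two observations per sample")
  if (paired) {
    if (length(a) != length(b)) stop("paired samples differ in length")
    d <- a - b
    if (stats::sd(d) == 0) {
      if (all(d == 0))
        return(list(t = 0, df = length(d) - 1, p.value = 1,
                    method = "Paired t test (degenerate: zero differences)"))
      stop("zero variance of the paired differences")
    }
    ht <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop("zero variance in both samples")
    ht <- stats::t.test(a, b, var.equal = !welch)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, method = ht$method)
}

# Pair treated/control rows of one property at one timepoint.
.pairRows <- function(tab, valueCol) {
  tr <- tab[tab$side == "treated", c("specimen", valueCol)]
  ct <- tab[tab$side == "control", c("specimen", valueCol)]
  miss <- union(setdiff(tr$specimen, ct$specimen),
                setdiff(ct$specimen, tr$specimen))
  if (length(miss) > 0)
    stop("unmatched treated/control pairs for specimen(s): ",
         paste(miss, collapse = ", "))
  m <- merge(tr, ct, by = "specimen", suffixes = c(".treated", ".control"))
  m <- m[order(m$specimen), ]
  list(specimen = m$specimen,
       treated = m[[paste0(valueCol, ".treated")]],
       control = m[[paste0(valueCol, ".control")]])
}

#' Paired treated-versus-control comparison of one property
#'
#' @param treated,control paired numeric vectors.
#' @param mode Wilcoxon mode, see [wilcoxonSignedRank].
#' @return a [PairedComparison-class].
#' @export
pairedComparison <- function(treated, control,
                             mode = c("asymptotic", "exact")) {
  test <- if (all(treated == control)) {
    # no difference in any pair: the signed-rank statistic is undefined
    list(statistic = NA_real_, Wplus = NA_real_, Wminus = NA_real_,
         z = NA_real_, p.value = NA_real_, nUsed = 0L,
         method = "Wilcoxon signed-rank (undefined: all differences zero)")
  } else wilcoxonSignedRank(treated, control, mode = mode)
  new("PairedComparison",
      pairs = cbind(treated = treated, control = control),
      differences = treated - control, ratios = treated / control,
      test = test)
}

#' Cohort report: group-level bending and micro-FE statistics
#'
#' Mirrors the standard reporting of a paired treated/control bone study:
#' per timepoint and property, the mean and sd of the per-pair
#' treated/control percent difference (e.g. "16 +/- 5 % less") and the
#' Wilcoxon signed-rank p-value; across timepoints, a two-sided t test on
#' the treated/control ratios.  The experimental stiffness is combined
#' with the FE stiffness into the back-calculated tissue modulus before
#' testing.
#'
#' @param mechTable data.frame with columns `specimen`, `timepoint`,
#'   `side` ("treated"/"control"), `stiffness_n_per_mm`, `yield_load_n`,
#'   `ultimate_load_n`.
#' @param feTable data.frame with columns `specimen`, `timepoint`, `side`,
#'   `fe_stiffness_n_per_mm`.
#' @param eRefGpa reference tissue modulus used in the FE models.
#' @param mode Wilcoxon mode.
#' @param alpha significance level recorded in the report.
#' @return list with `perTimepoint` and `acrossTimepoints` data.frames
#'   plus `alpha` and `eRefGpa`.
#' @export
cohortReport <- function(mechTable, feTable, eRefGpa = 10,
                         mode = c("asymptotic", "exact"), alpha = 0.05) {
  mode <- match.arg(mode)
  need <- c("specimen", "timepoint", "side", "stiffness_n_per_mm",
            "yield_load_n", "ultimate_load_n")
  if (!all(need %in% names(mechTable)))
    stop("mechTable lacks columns: ",
         paste(setdiff(need, names(mechTable)), collapse = ", "))
  needFe <- c("specimen", "timepoint", "side", "fe_stiffness_n_per_mm")
  if (!all(needFe %in% names(feTable)))
    stop("feTable lacks columns: ",
         paste(setdiff(needFe, names(feTable)), collapse = ", "))
  tab <- merge(mechTable, feTable,
               by = c("specimen", "timepoint", "side"))
  if (nrow(tab) < nrow(mechTable))
    stop("feTable is missing rows for: ",
         paste(setdiff(paste(mechTable$specimen, mechTable$side),
                       paste(tab$specimen, tab$side)), collapse = ", "))
  tab$e_tissue_gpa <- tab$stiffness_n_per_mm /
    tab$fe_stiffness_n_per_mm * eRefGpa
  props <- c("stiffness_n_per_mm", "yield_load_n", "ultimate_load_n",
             "fe_stiffness_n_per_mm", "e_tissue_gpa")
  per <- list()
  ratios <- list()
  for (tp in sort(unique(tab$timepoint))) {
    sub <- tab[tab$timepoint == tp, ]
    for (pr in props) {
      pp <- .pairRows(sub, pr)
      cmp <- pairedComparison(pp$treated, pp$control, mode = mode)
      pct <- (cmp@ratios - 1) * 100
      per[[length(per) + 1L]] <- data.frame(
        timepoint = tp, property = pr, n = length(pp$treated),
        mean_pct_diff = mean(pct), sd_pct_diff = stats::sd(pct),
        wilcoxon_T = cmp@test$statistic, z = cmp@test$z,
        p_value = cmp@test$p.value, stringsAsFactors = FALSE)
      ratios[[paste(tp, pr, sep = "\r")]] <- cmp@ratios
    }
  }
  perTimepoint <- do.call(rbind, per)
  tps <- sort(unique(tab$timepoint))
  across <- NULL
  if (length(tps) >= 2L) {
    rows <- lapply(props, function(pr) {
      r1 <- ratios[[paste(tps[1], pr, sep = "\r")]]
      r2 <- ratios[[paste(tps[2], pr, sep = "\r")]]
      # degenerate cohorts (zero ratio variance) are reported, not fatal
      tt <- tryCatch(twoSidedTTest(r1, r2), error = function(e)
        list(t = NA_real_, df = NA_real_, p.value = NA_real_))
      data.frame(property = pr, t = tt$t, df = tt$df,
                 p_value = tt$p.value, stringsAsFactors = FALSE)
    })
    across <- do.call(rbind, rows)
  }
  list(perTimepoint = perTimepoint, acrossTimepoints = across,
       alpha = alpha, eRefGpa = eRefGpa)
}
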