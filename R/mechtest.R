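#' @include constructors.R AllGenerics.R
NULL

# Best least-squares window by the max-R2 rule.  Candidate windows are
# contiguous runs of samples (up to the ultimate-load sample) whose force
# lies within the band, with length at least minFrac of all samples; among
# them the one maximizing R2 wins, ties broken by length then earliness.
.elasticWindow <- function(d, f, band = c(0.10, 0.60), minFrac = 0.15) {
  n <- length(f)
  iu <- which.max(f)
  fu <- f[iu]
  ok <- seq_len(iu)[f[seq_len(iu)] >= band[1] * fu &
                    f[seq_len(iu)] <= band[2] * fu]
  minLen <- max(3L, as.integer(ceiling(minFrac * n)))
  if (length(ok) == 0L) return(NULL)
  runs <- split(ok, cumsum(c(1L, diff(ok) != 1L)))
  best <- NULL
  for (run in runs) {
    m <- length(run)
    if (m < minLen) next
    x <- d[run]; y <- f[run]
    cx <- cumsum(x); cy <- cumsum(y)
    cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
    at <- function(c0, s, e) c0[e] - if (s > 1) c0[s - 1] else 0
    for (s in 1:(m - minLen + 1)) {
      for (e in (s + minLen - 1):m) {
        k <- e - s + 1
        Sx <- at(cx, s, e); Sy <- at(cy, s, e)
        Sxx <- at(cxx, s, e) - Sx^2 / k
        Syy <- at(cyy, s, e) - Sy^2 / k
        Sxy <- at(cxy, s, e) - Sx * Sy / k
        if (Sxx <= 0 || Syy <= 0) next
        slope <- Sxy / Sxx
        r2 <- min(1, Sxy^2 / (Sxx * Syy))
        cand <- list(start = run[s], end = run[e], slope = slope,
                     intercept = (Sy - slope * Sx) / k, r2 = r2, len = k)
        if (is.null(best) ||
            r2 > best$r2 + 1e-9 ||
            (abs(r2 - best$r2) <= 1e-9 &&
             (cand$len > best$len ||
              (cand$len == best$len && cand$start < best$start))))
          best <- cand
      }
    }
  }
  best
}

#' @describeIn analyzeCurve elastic stiffness of a raw curve.
#' @export
setMethod("elasticStiffness", "LoadDisplCurve",
  function(object, band = c(0.10, 0.60), minFrac = 0.15, ...) {
    fit <- .elasticWindow(object@displacementMm, object@forceN, band,
                          minFrac)
    if (is.null(fit))
      stop("no contiguous window of at least ", round(minFrac * 100),
           "% of samples lies within the force band [",
           band[1] * 100, "%, ", band[2] * 100, "%] of the ultimate load")
    structure(fit$slope, window = c(fit$start, fit$end), r2 = fit$r2,
              intercept = fit$intercept)
  })

#' @describeIn analyzeCurve ultimate load of a raw curve.
#' @export
setMethod("ultimateLoad", "LoadDisplCurve", function(object, ...) {
  i <- which.max(object@forceN)
  structure(object@forceN[i], index = i)
})

#' @describeIn analyzeCurve yield load of a raw curve; requires the
#'   elastic fit (computed on the fly if not supplied).
#' @export
setMethod("yieldLoad", "LoadDisplCurve",
  function(object, fit = NULL, deviationFraction = 0.05, ...) {
    if (is.null(fit)) fit <- elasticStiffness(object, ...)
    d <- object@displacementMm
    f <- object@forceN
    iu <- which.max(f)
    from <- attr(fit, "window")[2] + 1L
    yield <- f[iu]
    flagged <- TRUE
    if (from <= iu) {
      pred <- attr(fit, "intercept") + as.numeric(fit) * d[from:iu]
      dev <- (pred - f[from:iu]) / pmax(pred, .Machine$double.eps)
      hit <- which(pred > 0 & dev > deviationFraction)
      if (length(hit) > 0) {
        yield <- f[from + hit[1] - 1L]
        flagged <- FALSE
      }
    }
    structure(yield, atUltimate = flagged)
  })

#' Analyze a destructive three-point-bending curve
#'
#' Extracts the three whole-bone properties from a load-displacement
#' record:
#' \itemize{
#'   \item elastic stiffness — least-squares slope over the detected
#'     linear elastic range.  The window rule: among contiguous windows
#'     covering at least `minFrac` of the samples whose force lies in
#'     `band` (fractions of the ultimate load), choose the one maximizing
#'     R^2; ties go to the longest, then the earliest.  A best R^2 below
#'     0.9 sets the `"low_r2"` flag rather than failing silently.
#'   \item ultimate load — the maximum force sample.
#'   \item yield load — force at the changing point between the elastic
#'     and plastic ranges, i.e. at the first sample beyond the fit window
#'     where the measured force falls below the extrapolated elastic line
#'     by more than `deviationFraction` (relative).  A perfectly linear
#'     curve yields at the ultimate load and is flagged
#'     `"yield_at_ultimate"`.
#' }
#'
#' With `trimToeBelowN` set, leading samples below that force are dropped
#' and the displacement re-zeroed before analysis (machine toe-region
#' handling; off by default).
#'
#' @param curve a [LoadDisplCurve-class].
#' @param band force band for the elastic window, as fractions of the
#'   ultimate load.
#' @param minFrac minimum window length as a fraction of all samples.
#' @param deviationFraction relative departure from the elastic line that
#'   marks yield (default 0.05).
#' @param trimToeBelowN optional toe-region force cutoff (N).
#' @return a [MechSummary-class].
#' @examples
#' crv <- generateLoadCurve(curveSpec(100, 40, 60))
#' analyzeCurve(crv)
#' @export
analyzeCurve <- function(curve, band = c(0.10, 0.60), minFrac = 0.15,
                         deviationFraction = 0.05, trimToeBelowN = NULL) {
  stopifnot(is(curve, "LoadDisplCurve"))
  if (!is.null(trimToeBelowN)) {
    keep <- which(curve@forceN >= trimToeBelowN)[1]
    if (!is.na(keep) && keep > 1L) {
      d <- curve@displacementMm[keep:length(curve@forceN)]
      curve <- loadDisplCurve(d - d[1], curve@forceN[keep:length(curve@forceN)],
                              curve@metadata)
    }
  }
  fit <- elasticStiffness(curve, band = band, minFrac = minFrac)
  ult <- ultimateLoad(curve)
  yld <- yieldLoad(curve, fit = fit, deviationFraction = deviationFraction)
  flags <- character()
  if (attr(fit, "r2") < 0.9) flags <- c(flags, "low_r2")
  if (isTRUE(attr(yld, "atUltimate")))
    flags <- c(flags, "yield_at_ultimate")
  new("MechSummary",
      elasticStiffnessNPerMm = as.numeric(fit),
      yieldLoadN = as.numeric(yld), ultimateLoadN = as.numeric(ult),
      fitWindow = as.integer(attr(fit, "window")),
      fitR2 = attr(fit, "r2"), flags = flags, metadata = curve@metadata)
}

#' Read and write load-displacement curves as CSV
#'
#' The CSV contract is a header line `displacement_mm,force_n` followed by
#' numeric rows.  Malformed input fails with the offending line number.
#'
#' @param path CSV file.
#' @param metadata named list attached to the curve.
#' @return [readCurve]: a [LoadDisplCurve-class]; [writeCurve]: `path`.
#' @export
readCurve <- function(path, metadata = list()) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty curve file: ", path)
  header <- gsub("\\s", "", lines[1])
  if (header != "displacement_mm,force_n")
    stop("line 1 of ", path,
         ": expected header 'displacement_mm,force_n', got '", lines[1],
         "'")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no data rows in ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  n <- length(parts)
  d <- numeric(n); f <- numeric(n)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    v <- suppressWarnings(as.numeric(p))
    if (length(v) != 2L || any(is.na(v)))
      stop("malformed row at line ", i + 1L, " of ", path, ": '",
           body[i], "'")
    d[i] <- v[1]; f[i] <- v[2]
  }
  loadDisplCurve(d, f, metadata)
}

#' @rdname readCurve
#' @param curve a [LoadDisplCurve-class].
#' @export
writeCurve <- function(curve, path) {
  df <- data.frame(displacement_mm = curve@displacementMm,
                   force_n = curve@forceN)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a batch of curve files
#'
#' Analyzes every `*.csv` curve in a directory (or an explicit file list)
#' and returns one summary row per file.
#'
#' @param path directory containing curve CSV files, or a character vector
#'   of file paths.
#' @param ... passed to [analyzeCurve].
#' @return data.frame with columns `file`, `elastic_stiffness_n_per_mm`,
#'   `yield_load_n`, `ultimate_load_n`, `fit_r2`, `flags`.
#' @export
batchSummarize <- function(path, ...) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  else path
  files <- files[file.exists(files)]
  if (length(files) == 0L) stop("no curve files found in ", path)
  rows <- lapply(sort(files), function(fp) {
    s <- analyzeCurve(readCurve(fp), ...)
    data.frame(file = basename(fp),
               elastic_stiffness_n_per_mm = s@elasticStiffnessNPerMm,
               yield_load_n = s@yieldLoadN,
               ultimate_load_n = s@ultimateLoadN,
               fit_r2 = s@fitR2,
               flags = paste(s@flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
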