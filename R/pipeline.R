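#' @include imageproc.R microfe-solve.R mechtest.R calib.R
NULL

#' Default pipeline configuration
#'
#' Every stage parameter of the end-to-end chain, with the standard
#' defaults: reduce to 50 um, threshold at 500 per mille of the data
#' range, crop to the span between the bottom rollers plus 0.5 mm, tissue
#' modulus 10 GPa with Poisson ratio 0.3, solver tolerance 1e-6, and the
#' asymptotic Wilcoxon convention at alpha = 0.05.
#'
#' @return nested named list of stage blocks.
#' @export
defaultPipelineConfig <- function() {
  list(
    preprocessing = list(target_um = 50, permille = 500,
                         rollers_mm = c(1, 11), margin_mm = 0.5,
                         load_position_mm = NULL,
                         threshold_reference = "range"),
    fe = list(youngs_modulus_gpa = 10, poisson_ratio = 0.3, tol = 1e-6,
              max_iter = 50000, contact_halfwidth_vox = 1,
              prescribed_displacement_mm = -0.01),
    mechtest = list(band = c(0.10, 0.60), min_frac = 0.15,
                    yield_deviation_fraction = 0.05),
    stats = list(wilcoxon_mode = "asymptotic", alpha = 0.05,
                 e_ref_gpa = 10),
    seed = 1
  )
}

#' Validate (and complete) a pipeline configuration
#'
#' Unknown keys are rejected; omitted keys take their defaults; material
#' and threshold parameters are range-checked before any computation.
#'
#' @param config nested named list, e.g. from [readPipelineConfig].
#' @return the completed configuration list.
#' @export
validatePipelineConfig <- function(config) {
  ref <- defaultPipelineConfig()
  bad <- setdiff(names(config), names(ref))
  if (length(bad) > 0)
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "))
  for (blk in names(config)) {
    if (!is.list(ref[[blk]])) next
    badk <- setdiff(names(config[[blk]]), names(ref[[blk]]))
    if (length(badk) > 0)
      stop("unknown key(s) in '", blk, "': ",
           paste(badk, collapse = ", "))
    ref[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  if (!is.null(config$seed)) ref$seed <- config$seed
  # fail fast on invalid physics before any compute
  material(ref$fe$youngs_modulus_gpa, ref$fe$poisson_ratio)
  if (ref$preprocessing$permille <= 0 || ref$preprocessing$permille > 1000)
    stop("preprocessing$permille must lie in (0, 1000]")
  if (!ref$preprocessing$threshold_reference %in% c("range", "observed"))
    stop("threshold_reference must be 'range' or 'observed'")
  if (ref$fe$tol <= 0) stop("fe$tol must be positive")
  ref
}

#' @rdname validatePipelineConfig
#' @param path YAML configuration file.
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[bonefe] stage %-12s done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full image-to-statistics pipeline
#'
#' Executes preprocess -> micro-FE solve -> curve analysis -> tissue-
#' modulus calibration -> paired statistics on a set of specimens, writing
#' `summaries.csv`, `fe_results.csv`, `moduli.csv`, `report.json` and a
#' reproducibility manifest to the output directory.  All outputs are
#' deterministic functions of the inputs and configuration: a rerun with
#' the same seeds is bit-identical.
#'
#' @param config a validated configuration (see
#'   [validatePipelineConfig]).
#' @param specimens list of specimen records, each a list with elements
#'   `specimen`, `timepoint`, `side` ("treated"/"control"), `volume` (a
#'   [VoxelImage-class] or file path) and `curve` (a
#'   [LoadDisplCurve-class] or CSV path).
#' @param outputDir directory for result files (created if needed).
#' @return the [cohortReport] list, invisibly, with attribute `files`.
#' @export
runPipeline <- function(config, specimens, outputDir) {
  config <- validatePipelineConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  pp <- config$preprocessing
  fe <- config$fe
  mt <- config$mechtest
  st <- config$stats
  loadPos <- if (is.null(pp$load_position_mm)) mean(pp$rollers_mm)
             else pp$load_position_mm
  crop <- spanCrop(pp$rollers_mm, pp$margin_mm, loadPos)
  mat <- material(fe$youngs_modulus_gpa, fe$poisson_ratio)

  mechRows <- list(); feRows <- list(); modRows <- list()
  for (sp in specimens) {
    tag <- paste(sp$specimen, sp$timepoint, sp$side, sep = "/")
    vol <- if (is.character(sp$volume)) readVolume(sp$volume) else
      sp$volume
    crv <- if (is.character(sp$curve)) readCurve(sp$curve) else sp$curve
    mask <- .stage(paste0("preprocess ", tag), preprocessVolume(
      vol, crop, targetUm = pp$target_um, permille = pp$permille,
      reference = pp$threshold_reference))
    model <- buildModel(mask, mat, crop,
                        contactHalfwidthVox = fe$contact_halfwidth_vox,
                        prescribedDisplacementMm =
                          fe$prescribed_displacement_mm)
    sol <- .stage(paste0("solve      ", tag),
                  solveFE(model, tol = fe$tol, maxIter = fe$max_iter))
    summ <- .stage(paste0("bend       ", tag), analyzeCurve(
      crv, band = mt$band, minFrac = mt$min_frac,
      deviationFraction = mt$yield_deviation_fraction))
    modulus <- backCalculateTissueModulus(
      summ@elasticStiffnessNPerMm, feStiffness(sol), st$e_ref_gpa)
    base <- data.frame(specimen = sp$specimen, timepoint = sp$timepoint,
                       side = sp$side, stringsAsFactors = FALSE)
    mechRows[[tag]] <- cbind(base, data.frame(
      stiffness_n_per_mm = summ@elasticStiffnessNPerMm,
      yield_load_n = summ@yieldLoadN,
      ultimate_load_n = summ@ultimateLoadN, fit_r2 = summ@fitR2))
    feRows[[tag]] <- cbind(base, data.frame(
      fe_stiffness_n_per_mm = feStiffness(sol),
      iterations = sol@iterations, residual = sol@residual,
      n_elements = ncol(model@connectivity),
      n_nodes = nrow(model@nodeLattice)))
    modRows[[tag]] <- cbind(base, data.frame(
      k_exp_n_per_mm = modulus@kExpNPerMm,
      k_fe_n_per_mm = modulus@kFeNPerMm,
      e_tissue_gpa = modulus@eTissueGpa))
  }
  mechTable <- do.call(rbind, unname(mechRows))
  feTable <- do.call(rbind, unname(feRows))
  modTable <- do.call(rbind, unname(modRows))
  report <- .stage("stats", cohortReport(
    mechTable, feTable, eRefGpa = st$e_ref_gpa,
    mode = st$wilcoxon_mode, alpha = st$alpha))

  files <- file.path(outputDir, c("summaries.csv", "fe_results.csv",
                                  "moduli.csv", "report.json",
                                  "manifest.json",
                                  "report_per_timepoint.csv"))
  utils::write.csv(mechTable, files[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(feTable, files[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(modTable, files[3], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, files[4], auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows")
  utils::write.csv(report$perTimepoint, files[6], row.names = FALSE,
                   quote = FALSE)
  cfgPath <- file.path(outputDir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  manifest <- list(
    package = "bonefe",
    version = as.character(utils::packageVersion("bonefe")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfgPath)),
    n_specimens = length(specimens),
    specimens = vapply(specimens, function(sp)
      paste(sp$specimen, sp$timepoint, sp$side, sep = "/"), ""))
  jsonlite::write_json(manifest, files[5], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(structure(report, files = files))
}

# Analytic ground-truth stiffness of a phantom cross-section: the full
# mineralized annulus (woven shell + cortex + periosteal shell).
.phantomTrueStiffness <- function(pspec, spanMm, eGpa, nu = 0.3) {
  timoshenkoAnnulusStiffness(
    spanMm, material(eGpa, nu),
    pspec@outerRadiusMm + pspec@periostealThickeningMm,
    pspec@outerRadiusMm - pspec@corticalThicknessMm - pspec@wovenBoneMm)
}

#' Build the demonstration specimen set
#'
#' Synthetic paired cohort on reduced-size femur phantoms: per animal and
#' timepoint a control bone (plain hollow cylinder) and a treated bone
#' (endosteal woven-bone shell plus periosteal thickening).  The
#' "experimental" curves are generated from the closed-form Timoshenko
#' stiffness of each bone's annulus at a per-animal lognormal tissue
#' modulus, so the whole chain — including the tissue-modulus
#' back-calculation — has a known ground truth.
#'
#' @param seed master seed.
#' @param nPairs animal pairs per timepoint (default 2; `runDemo(full =
#'   TRUE)` uses 3).
#' @param voxelSizeUm phantom scan resolution (default 50; the pipeline
#'   reduces to 100 um for speed at demo scale).
#' @return list of specimen records for [runPipeline].
#' @export
demoSpecimens <- function(seed = 1, nPairs = 2, voxelSizeUm = 50) {
  specs <- list()
  # per-animal skeletal size variation (3% CV on radius and wall), shared
  # by the two sides of one animal; treated side adds the modeling shells
  geom <- function(sd, ro, th, treated) phantomSpec(
    lengthMm = 8, outerRadiusMm = ro, corticalThicknessMm = th,
    wovenBoneMm = if (treated) 0.15 else 0,
    periostealThickeningMm = if (treated) 0.1 else 0,
    voxelSizeUm = voxelSizeUm, blurSigmaUm = voxelSizeUm / 2,
    noiseSd = 0.02, seed = sd)
  span <- 6  # rollers at 1 and 7 mm on the 8 mm shaft
  tps <- c("7d", "1m")
  for (t in seq_along(tps)) {
    # per-animal tissue moduli: control lognormal, treated 5% lower
    cohort <- generatePairedCohort(pairedCohortSpec(
      nPairs = nPairs, controlMean = 13, controlCv = 0.05,
      treatmentEffect = -0.05, pairNoiseCv = 0.02,
      seed = as.integer(seed + 1000L * t)))
    for (p in seq_len(nPairs)) {
      size <- withr::with_seed(as.integer(seed + 1000L * t + 10L * p),
                               stats::rnorm(2, mean = 1, sd = 0.03))
      ro <- 1.2 * size[1]
      th <- 0.4 * size[2]
      for (side in c("control", "treated")) {
        sd <- as.integer(seed + 1000L * t + 10L * p +
                         (side == "treated"))
        ps <- geom(sd, ro, th, side == "treated")
        eTrue <- if (side == "control") cohort$control[p]
                 else cohort$treated[p]
        kTrue <- .phantomTrueStiffness(ps, span, eTrue)
        cs <- curveSpec(stiffnessNPerMm = kTrue,
                        yieldLoadN = 0.10 * kTrue,
                        ultimateLoadN = 0.13 * kTrue,
                        sampleIntervalS = 5,
                        noiseSdN = 0.002 * kTrue, seed = sd)
        specs[[length(specs) + 1L]] <- list(
          specimen = paste0("rat", p), timepoint = tps[t], side = side,
          volume = generateFemurPhantom(ps),
          curve = generateLoadCurve(cs, metadata = list(
            specimen = paste0("rat", p), side = side,
            timepoint = tps[t])),
          e_true_gpa = eTrue)
      }
    }
  }
  specs
}

#' Run the end-to-end demonstration pipeline
#'
#' Generates the demo cohort, runs the full chain and writes the result
#' bundle.  Reruns with the same seed are bit-identical.
#'
#' @param outputDir output directory.
#' @param seed master seed (default 1).
#' @param full use 3 animal pairs per timepoint instead of 2.
#' @return the report list, invisibly.
#' @export
runDemo <- function(outputDir, seed = 1, full = FALSE) {
  nPairs <- if (full) 3 else 2
  specimens <- .stage("phantoms", demoSpecimens(seed, nPairs))
  config <- defaultPipelineConfig()
  config$seed <- seed
  config$preprocessing$target_um <- 100
  config$preprocessing$rollers_mm <- c(1, 7)
  runPipeline(config, specimens, outputDir)
}
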