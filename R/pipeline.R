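#' Validate a run configuration
#'
#' A run configuration is a named list (typically read from a YAML file)
#' with input paths (`calls`, `reference`, `ancestral`, `cpg`, `tvGaps`,
#' `aaEffect`, `truth`, `confident`, `targets`), training settings
#' (`algorithms`, `cost` as `list(c1, c2)` or `NULL`, `k`, `policy` as
#' `list(tprMin, tnrMin)`, `testFraction`, `compact`), a `seed` and an
#' output directory `outDir`. All referenced paths must exist.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  pathKeys <- c("calls", "reference", "ancestral", "cpg", "tvGaps",
                "aaEffect", "truth", "confident", "targets", "model")
  for (k in intersect(pathKeys, names(config))) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      stop("configured path for '", k, "' does not exist: ", config[[k]])
    }
  }
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$k <- if (is.null(config$k)) 10L else as.integer(config$k)
  config$testFraction <- if (is.null(config$testFraction)) 0.33 else
    config$testFraction
  config
}

#' @keywords internal
.tracksFromConfig <- function(config) {
  GenomeTracks(
    reference = config$reference,
    ancestral = config$ancestral,
    cpgIslands = config$cpg,
    tvGaps = config$tvGaps,
    aaEffect = config$aaEffect
  )
}

#' @keywords internal
.datasetFromConfig <- function(config, matrices) {
  tracks <- .tracksFromConfig(config)
  records <- readSNVs(config$calls, sampleName = config$sampleName)
  if (!is.null(config$targets)) {
    records <- restrictToRegions(records, readBedRegions(config$targets))
  }
  ann <- annotateVariants(records, tracks)
  ds <- assembleDataset(records, ann, matrices)
  list(dataset = ds, tracks = tracks, records = records)
}

#' End-to-end training run
#'
#' Executes the full training workflow on a called VCF with truth data:
#' annotate, label against the truth set inside the confident regions,
#' duplicate-aware stratified train/test split, covariate-shift sanity
#' check, grid-searched stratified group CV (cost-sensitive when a cost is
#' configured), constrained model selection, final fit, held-out test
#' metrics, permutation importance, and optionally a median-pruned compact
#' model. Reports (CV table, split manifest, importance report, run
#' manifest with every seed) are written under `outDir`.
#'
#' @param config run configuration (list or YAML path), see
#'   [validateRunConfig()].
#' @return list with `model`, `compact` (or `NULL`), `cv`, `selection`,
#'   `testMetrics`, `shift`, `importance`, `outDir`.
#' @export
runTrain <- function(config) {
  config <- validateRunConfig(config)
  if (is.null(config$truth)) stop("runTrain requires a truth VCF ('truth')")
  outDir <- if (is.null(config$outDir)) tempfile("fpsieve_run_") else
    config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  matrices <- loadAminoAcidMatrices(config$aaMatrices)
  parts <- .datasetFromConfig(config, matrices)
  confident <- if (is.null(config$confident)) NULL else
    readBedRegions(config$confident)
  truth <- readSNVs(config$truth)
  labeled <- labelAgainstTruth(parts$dataset, truth, confident)

  split <- stratifiedGroupSplit(labeled, testFraction = config$testFraction,
                                seed = .childSeed(config$seed, 1L))
  shift <- covariateShiftCheck(split$train, split$test,
                               seed = .childSeed(config$seed, 2L))
  if (!shift$pass) {
    warning("covariate-shift check failed (AUC = ",
            sprintf("%.3f", shift$auc),
            "): train and test sets are distinguishable")
    if (isTRUE(config$abortOnShift)) stop("aborting on covariate shift")
  }
  cost <- if (is.null(config$cost)) NULL else
    costMatrix(config$cost$c1, config$cost$c2)
  policy <- if (is.null(config$policy)) selectionPolicy() else
    selectionPolicy(config$policy$tprMin, config$policy$tnrMin)
  grid <- defaultGrid(if (is.null(config$algorithms)) "rf" else
    config$algorithms)

  cv <- crossValidateGrid(split$train, grid, k = config$k, cost = cost,
                          seed = .childSeed(config$seed, 3L))
  sel <- selectModel(cv, policy)
  model <- trainFinal(split$train, sel$candidate, cost = cost,
                      seed = .childSeed(config$seed, 4L),
                      cvMetrics = sel$metrics)
  testMetrics <- if (nrow(split$test)) {
    computeMetrics(split$test$label, scoreVariants(model, split$test),
                   threshold = modelThreshold(model))
  } else NULL
  evalRows <- if (nrow(split$test)) split$test else split$train
  importance <- permutationImportance(model, evalRows,
                                      seed = .childSeed(config$seed, 5L))
  compact <- NULL
  if (isTRUE(config$compact)) {
    compact <- pruneToCompact(split$train, importance, grid, k = config$k,
                              cost = cost, policy = policy,
                              seed = .childSeed(config$seed, 6L))
  }

  saveFPModel(model, file.path(outDir, "model.rds"))
  if (!is.null(compact)) {
    saveFPModel(compact$model, file.path(outDir, "model_compact.rds"))
  }
  write.table(cv$summary, file.path(outDir, "cv_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(split$assignment, file.path(outDir, "split_manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeImportanceReport(importance, file.path(outDir, "importance.tsv"))
  manifest <- list(
    seed = config$seed,
    derivedSeeds = list(split = .childSeed(config$seed, 1L),
                        shift = .childSeed(config$seed, 2L),
                        cv = .childSeed(config$seed, 3L),
                        fit = .childSeed(config$seed, 4L),
                        importance = .childSeed(config$seed, 5L)),
    covariateShiftAUC = shift$auc,
    selected = sel$candidate,
    constrainedSelection = sel$constrained,
    cvMetrics = as.list(sel$metrics),
    testMetrics = if (is.null(testMetrics))
      NULL else testMetrics[c("tpr", "tnr", "auc_roc", "mcc")],
    compactFeatures = if (is.null(compact)) NULL else compact$retained
  )
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(model = model, compact = compact, cv = cv, selection = sel,
       testMetrics = testMetrics, shift = shift, importance = importance,
       split = split, outDir = outDir)
}

#' Score a VCF with a trained model
#'
#' Annotates and encodes the calls with the bundle's frozen encodings,
#' scores them, applies either a fixed threshold or a sensitivity-targeted
#' threshold tuned on a labeled calibration set (`truth` + `confident` in
#' the config), and writes a scored, filtered VCF.
#'
#' @param config run configuration with `model`, `calls`, track paths, an
#'   output `scoredVcf` path (default `<outDir>/scored.vcf`), and either
#'   `threshold` or `targetTpr` (+ truth inputs).
#' @return list with `records`, `scores`, `threshold`, `scoredVcf`.
#' @export
runPredict <- function(config) {
  config <- validateRunConfig(config)
  if (is.null(config$model)) stop("runPredict requires a fitted model path")
  model <- readFPModel(config$model)
  matrices <- loadAminoAcidMatrices(config$aaMatrices)
  parts <- .datasetFromConfig(config, matrices)
  scores <- scoreVariants(model, parts$dataset)
  threshold <- modelThreshold(model)
  if (!is.null(config$threshold)) {
    threshold <- config$threshold
  } else if (!is.null(config$targetTpr)) {
    if (is.null(config$truth)) {
      stop("targetTpr requires a truth set for calibration")
    }
    confident <- if (is.null(config$confident)) NULL else
      readBedRegions(config$confident)
    truth <- readSNVs(config$truth)
    cal <- labelAgainstTruth(parts$dataset, truth, confident)
    calScores <- scoreVariants(model, cal)
    threshold <- chooseThresholdForSensitivity(
      calScores, cal$label, config$targetTpr)$threshold
  }
  outDir <- if (is.null(config$outDir)) dirname(config$calls) else config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  scoredVcf <- if (is.null(config$scoredVcf))
    file.path(outDir, "scored.vcf") else config$scoredVcf
  writeScoredVcf(config$calls, parts$records, scores, threshold, scoredVcf)
  list(records = parts$records, scores = scores, threshold = threshold,
       scoredVcf = scoredVcf)
}
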