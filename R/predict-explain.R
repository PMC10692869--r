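## Encode an assembled dataset with a bundle's frozen encodings and predict.
#' @keywords internal
.scoreAssembled <- function(model, dataset) {
  enc <- c(model@encodings, list(oneHot = model@oneHot))
  xs <- .encodeForFit(model@algorithm, dataset, NULL, enc,
                      model@featureNames)
  .predictFit(model@algorithm, model@fit, xs$train)
}

#' Score variants with a fitted model
#'
#' Applies the bundle's frozen categorical encodings to the rows and returns
#' one probability per row that the call is a true variant (so values near 0
#' flag likely false positives). Deterministic given the bundle.
#'
#' @param model an [FPModel-class].
#' @param dataset assembled dataset rows (see [assembleDataset()]).
#' @return numeric scores in `[0, 1]`.
#' @export
scoreVariants <- function(model, dataset) {
  stopifnot(is(model, "FPModel"))
  need <- unique(.featureSourceColumn(model@featureNames))
  missing <- setdiff(need, names(dataset))
  if (length(missing)) {
    stop("dataset does not conform to the model's feature list; missing: ",
         paste(missing, collapse = ", "))
  }
  .scoreAssembled(model, dataset)
}

#' Choose a decision threshold for a required sensitivity
#'
#' Sweeps all candidate thresholds on a labeled calibration set and returns
#' the largest threshold `t` with `TPR(t) >= targetTpr`. Because TPR is
#' non-increasing and TNR non-decreasing in the threshold, this choice also
#' maximizes the FP recall among achieving thresholds. A target above the
#' achievable maximum (only possible for `targetTpr > 1`) falls back to the
#' minimum observed score with a warning flag.
#'
#' @param scores numeric scores in `[0, 1]` on the calibration set.
#' @param labels matching labels in `{0, 1}`.
#' @param targetTpr required sensitivity on true variants.
#' @return list with `threshold`, `achievedTpr`, `achievedTnr`,
#'   `targetReached`.
#' @export
chooseThresholdForSensitivity <- function(scores, labels, targetTpr = 0.99) {
  if (length(scores) == 0L) stop("empty calibration set")
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("calibration set must contain both classes")
  }
  cand <- sort(unique(scores))
  tprAt <- vapply(cand, function(t) mean(scores[labels == 1] >= t), numeric(1))
  ok <- tprAt >= targetTpr
  if (any(ok)) {
    t <- max(cand[ok])
    reached <- TRUE
  } else {
    t <- min(cand)
    reached <- FALSE
    warning("target TPR ", targetTpr, " unreachable; using minimal score")
  }
  m <- computeMetrics(labels, scores, threshold = t)
  list(threshold = t, achievedTpr = m$tpr, achievedTnr = m$tnr,
       targetReached = reached)
}

#' Permutation feature importance
#'
#' For each model feature, measures the mean drop in an evaluation metric
#' when that feature's column is randomly shuffled (within the dataset),
#' averaged over `nRepeats` independent, seeded shuffles. Shuffling is
#' applied to the underlying raw column (e.g. the Ref base for
#' `ref_frequency`), so categorical features are permuted coherently for
#' every algorithm.
#'
#' @param model an [FPModel-class].
#' @param dataset labeled assembled evaluation rows.
#' @param labels labels in `{0, 1}` (defaults to `dataset$label`).
#' @param metric `"auc_roc"`, `"tpr"`, `"tnr"` or `"mcc"` (default the
#'   selection objective, AUC-ROC).
#' @param nRepeats shuffles per feature (default 10).
#' @param seed integer seed.
#' @return list with `importance` (data.frame: `feature`, `mean_drop`,
#'   `sd_drop`, `rank`), `baseline`, `metric`, `nRepeats`, `seed`.
#' @export
permutationImportance <- function(model, dataset, labels = dataset$label,
                                  metric = "auc_roc", nRepeats = 10L,
                                  seed = 1L) {
  stopifnot(is(model, "FPModel"), nRepeats >= 1L)
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("importance metric undefined: labels contain a single class")
  }
  metricOf <- function(scores) {
    computeMetrics(labels, scores)[[metric]]
  }
  baseline <- metricOf(scoreVariants(model, dataset))
  feats <- model@featureNames
  drops <- matrix(NA_real_, nRepeats, length(feats),
                  dimnames = list(NULL, feats))
  .withSeed(seed, {
    for (f in feats) {
      col <- .featureSourceColumn(f)
      for (r in seq_len(nRepeats)) {
        shuffled <- dataset
        shuffled[[col]] <- sample(shuffled[[col]])
        drops[r, f] <- baseline - metricOf(scoreVariants(model, shuffled))
      }
    }
  })
  imp <- data.frame(feature = feats,
                    mean_drop = colMeans(drops),
                    sd_drop = apply(drops, 2L, sd))
  imp$rank <- rank(-imp$mean_drop, ties.method = "min")
  rownames(imp) <- NULL
  list(importance = imp, baseline = baseline, metric = metric,
       nRepeats = as.integer(nRepeats), seed = as.integer(seed))
}

#' @rdname permutationImportance
#' @param report an importance report.
#' @param path output TSV path.
#' @export
writeImportanceReport <- function(report, path) {
  write.table(report$importance, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Additive per-variant explanation (Shapley values)
#'
#' Attributes the difference between a variant's score and the expected
#' score over a background sample to the model features, using
#' interventional Shapley values estimated by averaging feature-insertion
#' paths over permutations of the feature order. When the number of features
#' is small enough (`factorial(p) <= maxExact`) all permutations are
#' enumerated and the attribution is exact. By construction the base value
#' plus the sum of contributions equals the variant's score (local accuracy,
#' up to floating-point error), for any number of sampled permutations.
#' Positive contributions push the score toward "true variant".
#'
#' @param model an [FPModel-class].
#' @param row a single assembled dataset row to explain.
#' @param background assembled dataset rows used as the reference
#'   distribution (non-empty).
#' @param nPerm permutations sampled when exact enumeration is infeasible
#'   (default 20).
#' @param maxExact enumerate all orderings when `factorial(p)` does not
#'   exceed this (default 720, i.e. up to 6 features).
#' @param seed integer seed for permutation sampling.
#' @return list with `baseValue`, `contributions` (named numeric over the
#'   model features), `score`.
#' @export
explainVariant <- function(model, row, background, nPerm = 20L,
                           maxExact = 720L, seed = 1L) {
  stopifnot(is(model, "FPModel"), nrow(row) == 1L)
  if (nrow(background) == 0L) stop("background sample must be non-empty")
  feats <- model@featureNames
  cols <- unique(.featureSourceColumn(feats))
  missing <- setdiff(cols, names(row))
  if (length(missing)) {
    stop("row does not conform to the model's feature list; missing: ",
         paste(missing, collapse = ", "))
  }
  p <- length(feats)
  perms <- if (factorial(p) <= maxExact) {
    .allPermutations(p)
  } else {
    .withSeed(seed, replicate(nPerm, sample.int(p), simplify = FALSE))
  }
  B <- nrow(background)
  nP <- length(perms)

  ## Build every hybrid row needed: for each permutation and background row,
  ## the chain background -> x obtained by flipping features in order.
  ## Prediction is batched into a single call.
  hybrids <- vector("list", nP)
  for (pi in seq_len(nP)) {
    ord <- perms[[pi]]
    chain <- vector("list", p)
    cur <- background
    for (step in seq_len(p)) {
      col <- .featureSourceColumn(feats[ord[step]])
      cur[[col]] <- rep(row[[col]], B)
      chain[[step]] <- cur
    }
    hybrids[[pi]] <- do.call(rbind, chain)
  }
  big <- rbind(background, do.call(rbind, hybrids))
  preds <- .scoreAssembled(model, big)

  basePreds <- preds[seq_len(B)]
  baseValue <- mean(basePreds)
  contrib <- stats::setNames(numeric(p), feats)
  offset <- B
  for (pi in seq_len(nP)) {
    ord <- perms[[pi]]
    prev <- basePreds
    for (step in seq_len(p)) {
      cur <- preds[offset + seq_len(B)]
      offset <- offset + B
      f <- feats[ord[step]]
      contrib[f] <- contrib[f] + mean(cur - prev) / nP
      prev <- cur
    }
  }
  score <- unname(.scoreAssembled(model, row))
  list(baseValue = baseValue, contributions = contrib, score = score)
}

#' @keywords internal
.allPermutations <- function(p) {
  if (p == 1L) return(list(1L))
  sub <- .allPermutations(p - 1L)
  out <- list()
  for (s in sub) {
    for (pos in 0:(p - 1L)) {
      out[[length(out) + 1L]] <- append(s, p, after = pos)
    }
  }
  out
}
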