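#' Constrained model-selection policy
#'
#' The selection rule used after cross-validation: among hyperparameter
#' candidates whose mean CV sensitivity and FP-recall strictly exceed the
#' thresholds (`TPR > tprMin` and `TNR > tnrMin`), the one maximizing
#' AUC-ROC wins. When no candidate qualifies, the fallback picks the
#' candidate with the highest TPR, ties broken by TNR, remaining ties by
#' candidate order.
#'
#' @param tprMin minimum sensitivity on true variants (default 0.99).
#' @param tnrMin minimum recall on false positives (default 0.40).
#' @return a policy list.
#' @export
selectionPolicy <- function(tprMin = 0.99, tnrMin = 0.40) {
  stopifnot(tprMin > 0, tprMin < 1, tnrMin > 0, tnrMin < 1)
  list(tprMin = tprMin, tnrMin = tnrMin, objective = "auc_roc")
}

#' Misclassification cost matrix
#'
#' Two costs drive cost-sensitive training: `c1`, the cost of letting a
#' false positive through (misclassifying an FP as true), and `c2`, the cost
#' of filtering out a true variant. Clinical use puts `c2 > c1`: losing a
#' true variant is worse than keeping an FP. Costs enter tree and logistic
#' fits as per-class observation weights.
#'
#' @param c1 cost of misclassifying a false positive (default 1).
#' @param c2 cost of misclassifying a true variant (default 4).
#' @return numeric vector `c(c1, c2)`.
#' @export
costMatrix <- function(c1 = 1, c2 = 4) {
  stopifnot(c1 > 0, c2 > 0)
  c(c1 = c1, c2 = c2)
}

#' Random undersampling of true variants
#'
#' Balances a training fold by randomly subsampling the true-variant rows
#' without replacement down to the number of FP rows; FP rows are never
#' touched. When the trues do not outnumber the FPs the fold is returned
#' unchanged. Reproducible under `seed`.
#'
#' @param dataset labeled rows (column `label`).
#' @param seed integer seed.
#' @return the balanced subset of `dataset`.
#' @export
undersampleMajority <- function(dataset, seed = 1L) {
  nFP <- sum(dataset$label == 0)
  nTP <- sum(dataset$label == 1)
  if (nFP == 0L) stop("cannot undersample: no false positives in fold")
  if (nTP <= nFP) return(dataset)
  keep <- .withSeed(seed, {
    tpIdx <- which(dataset$label == 1)
    sort(c(which(dataset$label == 0), sample(tpIdx, nFP)))
  })
  dataset[keep, , drop = FALSE]
}

#' Default hyperparameter grids
#'
#' Small, overridable grids for the three supported algorithms. A candidate
#' is a list with `algorithm` and `params`.
#'
#' @param algorithms which algorithms to include.
#' @return list of candidate lists.
#' @export
defaultGrid <- function(algorithms = c("rf", "dt", "logistic")) {
  grids <- list(
    rf = list(
      list(num.trees = 100L, mtry = NULL, min.node.size = 5L),
      list(num.trees = 300L, mtry = NULL, min.node.size = 1L)
    ),
    dt = list(
      list(cp = 0.01, maxdepth = 10L),
      list(cp = 0.001, maxdepth = 20L)
    ),
    logistic = list(list())
  )
  out <- list()
  for (alg in algorithms) {
    for (p in grids[[alg]]) {
      out[[length(out) + 1L]] <- list(algorithm = alg, params = p)
    }
  }
  out
}

## Fit one candidate on encoded features. Costs enter as per-class
## observation weights: c1 on FPs (label 0), c2 on true variants (label 1).
#' @keywords internal
.fitCandidate <- function(candidate, x, labels, cost, seed) {
  w <- if (is.null(cost)) rep(1, length(labels)) else
    ifelse(labels == 1, cost[["c2"]], cost[["c1"]])
  alg <- candidate$algorithm
  if (alg == "rf") {
    p <- candidate$params
    d <- cbind(x, .label = factor(labels, levels = c(0, 1)))
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = d,
      num.trees = if (is.null(p$num.trees)) 100L else p$num.trees,
      mtry = p$mtry,
      min.node.size = if (is.null(p$min.node.size)) 5L else p$min.node.size,
      probability = TRUE, case.weights = w, seed = seed, num.threads = 1L)
  } else if (alg == "dt") {
    p <- candidate$params
    d <- cbind(x, .label = factor(labels, levels = c(0, 1)))
    fit <- .withSeed(seed, rpart::rpart(
      .label ~ ., data = d, weights = w, method = "class",
      control = rpart::rpart.control(
        cp = if (is.null(p$cp)) 0.01 else p$cp,
        maxdepth = if (is.null(p$maxdepth)) 30L else p$maxdepth)))
  } else if (alg == "logistic") {
    d <- cbind(x, .label = labels)
    fit <- suppressWarnings(glm(.label ~ ., data = d,
                                family = quasibinomial(), weights = w))
  } else {
    stop("unknown algorithm: ", alg)
  }
  fit
}

#' @keywords internal
.predictFit <- function(algorithm, fit, x) {
  if (algorithm == "rf") {
    predict(fit, x, num.threads = 1L)$predictions[, "1"]
  } else if (algorithm == "dt") {
    predict(fit, x, type = "prob")[, "1"]
  } else {
    pmin(1, pmax(0, suppressWarnings(predict(fit, x, type = "response"))))
  }
}

## Encode train/eval partitions for one candidate: frequency encodings are
## fitted on the training rows only; logistic models replace the three
## frequency features with one-hot indicator blocks fitted the same way.
#' @keywords internal
.encodeForFit <- function(algorithm, trainSet, evalSet, encodings,
                          features = fpFeatureNames()) {
  if (algorithm == "logistic") {
    freqFeats <- intersect(features,
                           c("ref_frequency", "alt_frequency", "anc_frequency"))
    numFeats <- setdiff(features, freqFeats)
    buildX <- function(d) {
      x <- encodeFeatures(d, encodings, numFeats)
      for (f in freqFeats) {
        col <- .featureSourceColumn(f)
        x <- cbind(x, applyOneHot(encodings$oneHot[[col]], d[[col]],
                                  prefix = col))
      }
      x
    }
  } else {
    buildX <- function(d) encodeFeatures(d, encodings, features)
  }
  list(train = buildX(trainSet),
       eval = if (is.null(evalSet)) NULL else buildX(evalSet))
}

#' Grid-searched stratified group cross-validation
#'
#' For every hyperparameter candidate: each of `k` duplicate-aware,
#' class-stratified folds is held out in turn; the remaining rows are
#' balanced by undersampling the true variants, the categorical encodings
#' are fitted on those training rows only, the candidate is fitted (with
#' per-class cost weights when `cost` is given) and scored on the untouched
#' held-out fold. Per-fold metrics and their means are returned. A fold
#' failure aborts that candidate with a recorded reason, not the run.
#'
#' @param dataset labeled assembled dataset (`label`, `group` + feature
#'   columns).
#' @param grid list of candidates, e.g. from [defaultGrid()].
#' @param k number of folds (default 10).
#' @param cost `NULL` for traditional training or a [costMatrix()].
#' @param seed integer seed; every fold/candidate seed derives from it.
#' @param features feature subset to train on (default all 20).
#' @return a `CVResult`: list with `summary` (data.frame of mean metrics per
#'   candidate), `perFold`, `grid`, `folds`, `cost`, `seed`.
#' @export
crossValidateGrid <- function(dataset, grid, k = 10L, cost = NULL, seed = 1L,
                              features = fpFeatureNames()) {
  stopifnot(length(grid) > 0L)
  fold <- stratifiedGroupKFold(dataset, k = k, seed = .childSeed(seed, 0L))
  perFold <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (ci in seq_along(grid)) {
    cand <- grid[[ci]]
    res <- lapply(seq_len(k), function(f) {
      tryCatch({
        trainRows <- dataset[fold != f, , drop = FALSE]
        evalRows <- dataset[fold == f, , drop = FALSE]
        trainRows <- undersampleMajority(trainRows,
                                         seed = .childSeed(seed, ci * 1000L + f))
        enc <- fitEncodings(trainRows)
        xs <- .encodeForFit(cand$algorithm, trainRows, evalRows, enc, features)
        fit <- .fitCandidate(cand, xs$train, trainRows$label, cost,
                             seed = .childSeed(seed, ci * 2000L + f))
        scores <- .predictFit(cand$algorithm, fit, xs$eval)
        m <- computeMetrics(evalRows$label, scores)
        m[c("tpr", "tnr", "auc_roc", "mcc")]
      }, error = function(e) {
        .msg("candidate ", ci, " fold ", f, " failed: ", conditionMessage(e))
        list(tpr = NA_real_, tnr = NA_real_, auc_roc = NA_real_,
             mcc = NA_real_, error = conditionMessage(e))
      })
    })
    perFold[[ci]] <- res
    mt <- sapply(c("tpr", "tnr", "auc_roc", "mcc"), function(nm)
      mean(vapply(res, function(r) r[[nm]], numeric(1)), na.rm = FALSE))
    rows[[ci]] <- data.frame(candidate = ci, algorithm = cand$algorithm,
                             t(mt))
  }
  list(summary = do.call(rbind, rows), perFold = perFold, grid = grid,
       folds = fold, cost = cost, seed = as.integer(seed), k = as.integer(k))
}

#' Apply the constrained selection rule to a CV result
#'
#' @param cvResult result of [crossValidateGrid()].
#' @param policy a [selectionPolicy()].
#' @return list with `index`, `candidate`, `metrics` (named numeric) and
#'   `constrained` (whether the policy's constraints were satisfiable).
#' @export
selectModel <- function(cvResult, policy = selectionPolicy()) {
  s <- cvResult$summary
  stopifnot(nrow(s) > 0L)
  ok <- !is.na(s$tpr) & !is.na(s$tnr) &
    s$tpr > policy$tprMin & s$tnr > policy$tnrMin
  if (any(ok, na.rm = TRUE)) {
    cand <- s[ok, , drop = FALSE]
    best <- cand$candidate[which.max(cand$auc_roc)]
    constrained <- TRUE
  } else {
    usable <- s[!is.na(s$tpr), , drop = FALSE]
    if (nrow(usable) == 0L) stop("no candidate produced valid CV metrics")
    ord <- order(-usable$tpr, -usable$tnr, usable$candidate)
    best <- usable$candidate[ord[1L]]
    constrained <- FALSE
  }
  metrics <- unlist(s[s$candidate == best, c("tpr", "tnr", "auc_roc", "mcc")])
  list(index = best, candidate = cvResult$grid[[best]],
       metrics = metrics, constrained = constrained)
}

#' Fit the final model on the full training set
#'
#' Refits the selected candidate on the whole training partition after one
#' undersampling pass, with the same cost weighting used during CV. The
#' frequency encodings are fitted on the full training partition (before
#' undersampling) and frozen into the returned bundle so that prediction
#' never re-fits them.
#'
#' @param dataset labeled assembled training dataset.
#' @param candidate selected candidate (from [selectModel()]`$candidate` or
#'   hand-built).
#' @param cost `NULL` or a [costMatrix()].
#' @param seed integer seed.
#' @param features feature subset (default all 20).
#' @param cvMetrics optional named numeric of the candidate's CV metrics to
#'   record in the bundle.
#' @param threshold decision threshold stored in the bundle (default 0.5).
#' @return an [FPModel-class].
#' @export
trainFinal <- function(dataset, candidate, cost = NULL, seed = 1L,
                       features = fpFeatureNames(),
                       cvMetrics = numeric(0), threshold = 0.5) {
  enc <- fitEncodings(dataset)
  fitRows <- undersampleMajority(dataset, seed = .childSeed(seed, 99L))
  xs <- .encodeForFit(candidate$algorithm, fitRows, NULL, enc, features)
  fit <- .fitCandidate(candidate, xs$train, fitRows$label, cost,
                       seed = .childSeed(seed, 100L))
  new("FPModel",
      algorithm = candidate$algorithm,
      fit = fit,
      params = if (is.null(candidate$params)) list() else candidate$params,
      featureNames = features,
      encodings = enc[c("ref", "alt", "anc")],
      oneHot = if (candidate$algorithm == "logistic") enc$oneHot else NULL,
      threshold = threshold,
      cost = cost,
      cvMetrics = cvMetrics,
      seed = as.integer(seed),
      version = "1")
}

#' Prune a model to the features at or above median importance
#'
#' Retains the features whose permutation importance is greater than or
#' equal to the median importance (so with all-equal importances everything
#' is retained), then re-runs the CV grid search and constrained selection
#' on the reduced feature set and refits. The result is a compact bundle
#' recording its retained feature list.
#'
#' @param dataset labeled assembled training dataset.
#' @param importanceReport report from [permutationImportance()].
#' @param grid candidate grid for the re-search.
#' @param k CV folds.
#' @param cost `NULL` or [costMatrix()].
#' @param policy [selectionPolicy()] for the re-selection.
#' @param seed integer seed.
#' @return list with `model` (compact [FPModel-class]), `retained`
#'   (character), `cv` and `selection`.
#' @export
pruneToCompact <- function(dataset, importanceReport, grid, k = 10L,
                           cost = NULL, policy = selectionPolicy(),
                           seed = 1L) {
  imp <- importanceReport$importance
  med <- median(imp$mean_drop)
  retained <- imp$feature[imp$mean_drop >= med]
  retained <- fpFeatureNames()[fpFeatureNames() %in% retained]
  if (length(retained) < 2L) {
    stop("pruning left fewer than 2 features; refusing to build a model")
  }
  cv <- crossValidateGrid(dataset, grid, k = k, cost = cost, seed = seed,
                          features = retained)
  sel <- selectModel(cv, policy)
  model <- trainFinal(dataset, sel$candidate, cost = cost, seed = seed,
                      features = retained, cvMetrics = sel$metrics)
  list(model = model, retained = retained, cv = cv, selection = sel)
}
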