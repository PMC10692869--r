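#' Label called variants against a truth set
#'
#' Restricts calls to the high-confidence regions and labels each remaining
#' record 1 when its exact `(chrom, pos, ref, alt)` key is present in the
#' truth set and 0 (false positive) otherwise. Calls outside the confident
#' regions are excluded, never labeled: outside those regions the truth set
#' makes no claim. Matching is exact by key; no haplotype-aware
#' normalization is attempted.
#'
#' @param records SNV records (or an assembled dataset) with
#'   `chrom, pos, ref, alt` columns.
#' @param truth truth-set records (e.g. [readSNVs()] on the truth VCF), or a
#'   character vector of `chrom:pos:ref:alt` keys.
#' @param confidentRegions `GRanges` of high-confidence regions, or `NULL`
#'   to label everything.
#' @return the retained rows with a new `label` column (1 = true variant,
#'   0 = false positive) and a `group` column of variant keys.
#' @export
labelAgainstTruth <- function(records, truth, confidentRegions = NULL) {
  truthKeys <- if (is.character(truth)) truth else
    variantKey(truth$chrom, truth$pos, truth$ref, truth$alt)
  if (length(truthKeys) == 0L) {
    stop("empty truth set: nothing to label against")
  }
  if (!is.null(confidentRegions)) {
    records <- restrictToRegions(records, confidentRegions)
  }
  key <- variantKey(records$chrom, records$pos, records$ref, records$alt)
  records$group <- key
  records$label <- as.numeric(key %in% truthKeys)
  rownames(records) <- NULL
  records
}

## Group-level view of a labeled dataset: one row per variant key with its
## class label and row count. Duplicate rows of one variant always share a
## label (same truth-set membership), enforced here.
#' @keywords internal
.groupTable <- function(dataset) {
  stopifnot(all(c("group", "label") %in% names(dataset)))
  agg <- aggregate(list(n = dataset$label), by = list(group = dataset$group),
                   FUN = length)
  lab <- aggregate(list(label = dataset$label),
                   by = list(group = dataset$group), FUN = function(x) {
                     u <- unique(x)
                     if (length(u) > 1L) {
                       stop("variant group with inconsistent labels: ",
                            "duplicates of one variant must share a label")
                     }
                     u
                   })
  merge(agg, lab, by = "group")
}

#' Duplicate-aware stratified train/test split
#'
#' Splits a labeled dataset into train and test partitions such that (a)
#' every variant key (duplicate calls from different kits) lands wholly in
#' one partition, and (b) each class's share of rows in the test partition
#' approximates `testFraction` (the per-class row proportions of the full
#' dataset are preserved to within a couple of percentage points for
#' realistically sized data). Reproducible under `seed`.
#'
#' @param dataset labeled dataset with `group` and `label` columns.
#' @param testFraction fraction of rows assigned to the test partition
#'   (default 0.33, i.e. a 67:33 split).
#' @param seed integer seed.
#' @return list with data.frames `train` and `test` and an `assignment`
#'   data.frame (`group`, `partition`).
#' @export
stratifiedGroupSplit <- function(dataset, testFraction = 0.33, seed = 1L) {
  stopifnot(testFraction >= 0, testFraction < 1)
  gt <- .groupTable(dataset)
  if (testFraction == 0) {
    assignment <- data.frame(group = gt$group, partition = "train")
  } else {
    assignment <- .withSeed(seed, {
      parts <- lapply(split(gt, gt$label), function(g) {
        g <- g[sample.int(nrow(g)), , drop = FALSE]
        target <- testFraction * sum(g$n)
        csum <- cumsum(g$n)
        nTest <- sum(csum <= target)
        ## take one more group when that lands us nearer the target
        if (nTest < nrow(g) &&
            abs(csum[nTest + 1L] - target) <
              abs((if (nTest == 0L) 0 else csum[nTest]) - target)) {
          nTest <- nTest + 1L
        }
        data.frame(group = g$group,
                   partition = rep(c("test", "train"),
                                   c(nTest, nrow(g) - nTest)))
      })
      do.call(rbind, parts)
    })
    merged <- merge(gt, assignment, by = "group")
    perClass <- table(factor(merged$label),
                      factor(merged$partition, levels = c("train", "test")))
    if (any(perClass == 0)) {
      stop("infeasible stratification: a class is absent from one partition ",
           "(group structure too coarse for testFraction = ", testFraction,
           "); per-class group counts: ",
           paste(table(gt$label), collapse = ", "))
    }
  }
  part <- assignment$partition[match(dataset$group, assignment$group)]
  list(train = dataset[part == "train", , drop = FALSE],
       test = dataset[part == "test", , drop = FALSE],
       assignment = assignment)
}

#' Duplicate-aware stratified k-fold assignment
#'
#' Partitions the variant groups into `k` folds so that duplicates never
#' span folds and each fold's class composition tracks the global one:
#' within each class, groups are assigned greedily (largest first, random
#' tie order under `seed`) to the fold currently holding the fewest rows of
#' that class.
#'
#' @param dataset labeled dataset with `group` and `label` columns.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), one per dataset row.
#' @export
stratifiedGroupKFold <- function(dataset, k = 10L, seed = 1L) {
  gt <- .groupTable(dataset)
  perClassGroups <- table(gt$label)
  if (any(perClassGroups < k)) {
    stop("cannot build ", k, " folds: a class has only ",
         min(perClassGroups), " variant group(s)")
  }
  foldOf <- .withSeed(seed, {
    out <- stats::setNames(integer(nrow(gt)), gt$group)
    for (g in split(gt, gt$label)) {
      g <- g[sample.int(nrow(g)), , drop = FALSE]
      g <- g[order(-g$n), , drop = FALSE]
      load <- numeric(k)
      for (i in seq_len(nrow(g))) {
        f <- which.min(load)
        load[f] <- load[f] + g$n[i]
        out[g$group[i]] <- f
      }
    }
    out
  })
  unname(foldOf[dataset$group])
}

#' Covariate-shift check between train and test partitions
#'
#' Adversarial validation: a logistic discriminator is trained (with
#' internal cross-validation) to predict whether a row belongs to the test
#' partition, using the model features only — never the class label. An
#' out-of-fold AUC near 0.5 means the partitions are statistically
#' indistinguishable, i.e. the split generalizes; the check flags PASS when
#' the AUC does not exceed `passThreshold` (default 0.55, allowing for
#' sampling noise around the ideal 0.5).
#'
#' @param train,test assembled (labeled or unlabeled) dataset partitions.
#' @param seed integer seed for the internal folds.
#' @param passThreshold AUC above which the check fails.
#' @param nFolds internal CV folds for the discriminator.
#' @return list with `auc`, `pass`, `nTrain`, `nTest`.
#' @export
covariateShiftCheck <- function(train, test, seed = 1L, passThreshold = 0.55,
                                nFolds = 5L) {
  if (nrow(train) < 2L || nrow(test) < 2L) {
    stop("degenerate partition: need at least 2 rows in train and test")
  }
  pooled <- rbind(train[intersect(names(train), names(test))],
                  test[intersect(names(train), names(test))])
  pooled$label <- NULL
  y <- rep(c(0, 1), c(nrow(train), nrow(test)))
  enc <- fitEncodings(pooled)
  x <- encodeFeatures(pooled, enc)
  probs <- .withSeed(seed, {
    fold <- sample(rep_len(seq_len(nFolds), nrow(x)))
    p <- numeric(nrow(x))
    for (f in seq_len(nFolds)) {
      inTrain <- fold != f
      fit <- suppressWarnings(glm(y[inTrain] ~ ., family = binomial(),
                                  data = x[inTrain, , drop = FALSE]))
      p[!inTrain] <- suppressWarnings(
        predict(fit, x[!inTrain, , drop = FALSE], type = "response"))
    }
    p
  })
  auc <- .aucRank(y, probs)
  list(auc = auc, pass = auc <= passThreshold,
       nTrain = nrow(train), nTest = nrow(test))
}
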