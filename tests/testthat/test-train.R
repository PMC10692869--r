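test_that("metric suite matches closed-form values", {
  # perfect separation
  m <- computeMetrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(m$tpr, 1)
  expect_equal(m$tnr, 1)
  expect_equal(m$auc_roc, 1)
  expect_equal(m$mcc, 1)

  # confusion counts TP=90 FN=10 TN=40 FP=60: MCC = 3000/sqrt(150*100*100*50)
  labels <- rep(c(1, 1, 0, 0), c(90, 10, 40, 60))
  scores <- rep(c(0.9, 0.1, 0.1, 0.9), c(90, 10, 40, 60))
  m2 <- computeMetrics(labels, scores)
  expect_equal(m2$tpr, 0.9)
  expect_equal(m2$tnr, 0.4)
  expect_equal(m2$mcc, 3000 / sqrt(150 * 100 * 100 * 50), tolerance = 1e-12)
  expect_equal(unname(m2$counts), c(90, 10, 40, 60))

  # null behavior: random scores near AUC 0.5
  withr::with_seed(1, {
    lab <- rep(c(0, 1), 5000L)
    m3 <- computeMetrics(lab, runif(10000L))
    expect_gt(m3$auc_roc, 0.48)
    expect_lt(m3$auc_roc, 0.52)
  })

  # single-class labels: AUC undefined, others computed
  m4 <- computeMetrics(c(1, 1), c(0.6, 0.7))
  expect_true(is.na(m4$auc_roc))
  expect_equal(m4$tpr, 1)
})

test_that("rank-statistic AUC agrees with an independent ROC implementation", {
  withr::with_seed(42, {
    labels <- rbinom(300L, 1L, 0.4)
    scores <- runif(300L)
    scores[labels == 1] <- scores[labels == 1] + rnorm(sum(labels), 0.3, 0.2)
    scores <- pmin(1, pmax(0, scores))
    ours <- computeMetrics(labels, scores)$auc_roc
    ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})

test_that("undersampling balances classes by subsampling trues only", {
  ds <- data.frame(label = rep(c(1, 0), c(800L, 200L)), id = 1:1000)
  b <- undersampleMajority(ds, seed = 5L)
  expect_equal(sum(b$label == 1), 200L)
  expect_equal(sum(b$label == 0), 200L)
  expect_true(all(ds$id[ds$label == 0] %in% b$id))
  expect_identical(b, undersampleMajority(ds, seed = 5L))
  expect_false(identical(b$id, undersampleMajority(ds, seed = 6L)$id))
  balanced <- data.frame(label = c(1, 0), id = 1:2)
  expect_identical(undersampleMajority(balanced, seed = 1L), balanced)
  expect_error(undersampleMajority(data.frame(label = c(1, 1)), 1L),
               "no false positives")
})

test_that("constrained selection applies thresholds then falls back", {
  mkcv <- function(df) {
    list(summary = cbind(candidate = seq_len(nrow(df)), algorithm = "rf", df),
         grid = lapply(seq_len(nrow(df)), function(i)
           list(algorithm = "rf", params = list(id = i))))
  }
  # only the first candidate satisfies both constraints
  cv <- mkcv(data.frame(tpr = c(0.995, 0.96), tnr = c(0.45, 0.58),
                        auc_roc = c(0.83, 0.86), mcc = c(0.5, 0.55)))
  sel <- selectModel(cv)
  expect_equal(sel$index, 1L)
  expect_true(sel$constrained)

  # none satisfies: max TPR, ties broken by TNR
  cv2 <- mkcv(data.frame(tpr = c(0.98, 0.98), tnr = c(0.30, 0.35),
                         auc_roc = c(0.9, 0.7), mcc = c(0.5, 0.5)))
  sel2 <- selectModel(cv2)
  expect_equal(sel2$index, 2L)
  expect_false(sel2$constrained)
})

test_that("selection matches a brute-force scan on random candidate lists", {
  policy <- selectionPolicy()
  withr::with_seed(77, {
    for (rep in 1:100) {
      k <- sample(2:8, 1L)
      df <- data.frame(tpr = round(runif(k, 0.9, 1), 3),
                       tnr = round(runif(k, 0.2, 0.7), 3),
                       auc_roc = round(runif(k, 0.6, 1), 3),
                       mcc = runif(k))
      cv <- list(summary = cbind(candidate = 1:k, algorithm = "rf", df),
                 grid = lapply(1:k, function(i) list(algorithm = "rf",
                                                     params = list(id = i))))
      got <- selectModel(cv, policy)$index
      # oracle: exhaustive scan over candidates
      feasible <- which(df$tpr > policy$tprMin & df$tnr > policy$tnrMin)
      expected <- if (length(feasible)) {
        feasible[which.max(df$auc_roc[feasible])]
      } else {
        best <- order(-df$tpr, -df$tnr, seq_len(k))[1L]
        best
      }
      expect_equal(got, expected)
    }
  })
})

test_that("cross-validation bookkeeping and determinism", {
  ds <- smallDataset(n = 600L, seed = 23L)
  grid <- defaultGrid("rf")[1]
  cv <- crossValidateGrid(ds, grid, k = 2L, seed = 3L)
  expect_equal(nrow(cv$summary), 1L)
  expect_length(cv$perFold[[1L]], 2L)
  expect_setequal(unique(cv$folds), 1:2)
  cv2 <- crossValidateGrid(ds, grid, k = 2L, seed = 3L)
  expect_identical(cv$summary, cv2$summary)
  # fold assignment partitions the rows (no leakage by construction):
  # every row is evaluated exactly once
  expect_length(cv$folds, nrow(ds))
})

test_that("final fit is deterministic and scores stay in [0, 1]", {
  ds <- smallDataset(n = 800L, seed = 29L)
  cand <- list(algorithm = "rf", params = list(num.trees = 100L))
  m1 <- trainFinal(ds, cand, seed = 4L)
  m2 <- trainFinal(ds, cand, seed = 4L)
  s1 <- scoreVariants(m1, ds)
  expect_identical(s1, scoreVariants(m2, ds))
  expect_true(all(s1 >= 0 & s1 <= 1))
  # serialized bundles with equal seeds are identical
  p1 <- tempfile(); p2 <- tempfile()
  saveFPModel(m1, p1); saveFPModel(m2, p2)
  expect_identical(readLines(paste0(p1, ".json")),
                   readLines(paste0(p2, ".json")))
})

test_that("all three algorithms train and score on the same dataset", {
  ds <- smallDataset(n = 700L, seed = 31L)
  for (alg in c("rf", "dt", "logistic")) {
    cand <- defaultGrid(alg)[[1L]]
    m <- trainFinal(ds, cand, seed = 2L)
    s <- scoreVariants(m, ds)
    expect_true(all(s >= 0 & s <= 1), info = alg)
    expect_gt(computeMetrics(ds$label, s)$auc_roc, 0.8)
  }
})

test_that("cost-sensitive weighting shifts the operating point toward TPR", {
  ds <- smallDataset(n = 2000L, preset = "hard", seed = 37L)
  sp <- stratifiedGroupSplit(ds, seed = 1L)
  cand <- list(algorithm = "rf", params = list(num.trees = 100L))
  trad <- trainFinal(sp$train, cand, seed = 5L)
  cs <- trainFinal(sp$train, cand, cost = costMatrix(1, 4), seed = 5L)
  mTrad <- computeMetrics(sp$test$label, scoreVariants(trad, sp$test))
  mCs <- computeMetrics(sp$test$label, scoreVariants(cs, sp$test))
  expect_gt(mCs$tpr, mTrad$tpr)
  expect_lt(mCs$tnr, mTrad$tnr)
})

test_that("median pruning retains exactly the features at/above the median", {
  ds <- smallDataset(n = 1500L, seed = 41L)
  sp <- stratifiedGroupSplit(ds, seed = 2L)
  grid <- defaultGrid("rf")[1]
  cv <- crossValidateGrid(sp$train, grid, k = 3L, seed = 6L)
  sel <- selectModel(cv)
  model <- trainFinal(sp$train, sel$candidate, seed = 6L)
  imp <- permutationImportance(model, sp$test, nRepeats = 3L, seed = 7L)
  pruned <- pruneToCompact(sp$train, imp, grid, k = 3L, seed = 8L)
  med <- median(imp$importance$mean_drop)
  expected <- imp$importance$feature[imp$importance$mean_drop >= med]
  expect_setequal(pruned$retained, expected)
  expect_setequal(modelFeatures(pruned$model), expected)
  # all-equal importances retain everything
  fake <- imp
  fake$importance$mean_drop <- 1
  prunedAll <- pruneToCompact(sp$train, fake, grid, k = 3L, seed = 8L)
  expect_setequal(prunedAll$retained, fpFeatureNames())
})

test_that("FPModel validity and accessors behave", {
  ds <- smallDataset(n = 400L, seed = 43L)
  m <- trainFinal(ds, defaultGrid("rf")[[1L]], seed = 1L)
  expect_equal(modelAlgorithm(m), "rf")
  expect_length(modelFeatures(m), 20L)
  expect_equal(modelThreshold(m), 0.5)
  modelThreshold(m) <- 0.3
  expect_equal(modelThreshold(m), 0.3)
  expect_error({ modelThreshold(m) <- 1.5 }, "threshold")
  expect_output(show(m), "FPModel")
  # round-trip through the archive
  p <- tempfile()
  saveFPModel(m, p)
  m2 <- readFPModel(p)
  expect_identical(scoreVariants(m2, ds), scoreVariants(m, ds))
})
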