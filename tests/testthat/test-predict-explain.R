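test_that("scoring is deterministic and enforces the feature schema", {
  ds <- smallDataset(n = 600L, seed = 51L)
  m <- trainFinal(ds, defaultGrid("rf")[[1L]], seed = 1L)
  s1 <- scoreVariants(m, ds)
  expect_identical(s1, scoreVariants(m, ds))
  broken <- ds
  broken$anc <- NULL
  expect_error(scoreVariants(m, broken), "anc")
  # scores separate the classes on this moderately separable data
  expect_gt(computeMetrics(ds$label, s1)$auc_roc, 0.9)
})

test_that("sensitivity-targeted threshold matches a brute-force sweep", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      n <- 300L
      labels <- rbinom(n, 1L, 0.7)
      scores <- round(pmin(1, pmax(0, rnorm(n, 0.3 + 0.3 * labels, 0.2))), 3)
      if (!any(labels == 1) || !any(labels == 0)) next
      target <- sample(c(0.9, 0.95, 0.99, 1), 1L)
      got <- chooseThresholdForSensitivity(scores, labels, target)
      # oracle: evaluate TPR at every candidate threshold
      cand <- sort(unique(scores))
      tprAt <- vapply(cand, function(t) mean(scores[labels == 1] >= t),
                      numeric(1))
      expected <- max(cand[tprAt >= target])
      expect_equal(got$threshold, expected)
      expect_gte(got$achievedTpr, target)
      # the returned threshold maximizes TNR among achieving thresholds
      tnrAt <- vapply(cand[tprAt >= target],
                      function(t) mean(scores[labels == 0] < t), numeric(1))
      expect_equal(got$achievedTnr, max(tnrAt))
    }
  })
  expect_error(chooseThresholdForSensitivity(numeric(0), numeric(0)), "empty")
  expect_error(chooseThresholdForSensitivity(c(0.5), c(1)), "both classes")
})

test_that("permutation importance separates signal from noise", {
  ds <- smallDataset(n = 1200L, seed = 53L)
  sp <- stratifiedGroupSplit(ds, seed = 1L)
  m <- trainFinal(sp$train, defaultGrid("rf")[[1L]], seed = 2L)
  rep1 <- permutationImportance(m, sp$test, nRepeats = 3L, seed = 5L)
  expect_equal(nrow(rep1$importance), 20L)
  expect_setequal(rep1$importance$feature, fpFeatureNames())
  # reproducible under the seed
  rep2 <- permutationImportance(m, sp$test, nRepeats = 3L, seed = 5L)
  expect_identical(rep1$importance, rep2$importance)
  # qd carries strong class signal; family_pair none (same dist per class)
  imp <- rep1$importance
  expect_gt(imp$mean_drop[imp$feature == "qd"],
            imp$mean_drop[imp$feature == "family_pair"])
  noise <- imp[imp$feature == "family_pair", ]
  expect_lt(abs(noise$mean_drop), max(2 * noise$sd_drop, 0.01))
  expect_error(permutationImportance(m, sp$test[sp$test$label == 1, ]),
               "single class")
})

test_that("explanations satisfy local accuracy", {
  ds <- smallDataset(n = 700L, seed = 57L)
  m <- trainFinal(ds, defaultGrid("rf")[[1L]], seed = 3L)
  bg <- ds[1:25, ]
  for (i in c(30L, 31L, 32L, 400L)) {
    ex <- explainVariant(m, ds[i, , drop = FALSE], bg, nPerm = 2L, seed = 9L)
    expect_equal(ex$baseValue + sum(ex$contributions), ex$score,
                 tolerance = 1e-6)
    expect_named(ex$contributions, modelFeatures(m), ignore.order = FALSE)
  }
  # base value is the mean background score
  ex <- explainVariant(m, ds[30L, , drop = FALSE], bg, nPerm = 2L, seed = 9L)
  expect_equal(ex$baseValue, mean(scoreVariants(m, bg)), tolerance = 1e-12)
})

test_that("explanations agree with exhaustive Shapley enumeration", {
  # a 3-feature model is small enough for the exact coalition formula
  ds <- smallDataset(n = 200L, seed = 59L)
  feats <- c("qd", "mq", "fs")
  m <- trainFinal(ds, defaultGrid("rf")[[1L]], seed = 1L, features = feats)
  row <- ds[7L, , drop = FALSE]
  bg <- ds[21:40, ]
  ex <- explainVariant(m, row, bg, seed = 3L)  # 3! = 6 orders: exact
  # oracle: interventional Shapley by coalition enumeration over 2^3 subsets
  valueOf <- function(S) {
    hyb <- bg
    for (f in S) hyb[[f]] <- rep(row[[f]], nrow(bg))
    mean(scoreVariants(m, hyb))
  }
  shap <- sapply(feats, function(f) {
    others <- setdiff(feats, f)
    subsets <- unlist(lapply(0:length(others), function(k)
      combn(others, k, simplify = FALSE)), recursive = FALSE)
    sum(vapply(subsets, function(S) {
      s <- length(S)
      w <- factorial(s) * factorial(length(feats) - s - 1) /
        factorial(length(feats))
      w * (valueOf(c(S, f)) - valueOf(S))
    }, numeric(1)))
  })
  expect_equal(unname(ex$contributions[feats]), unname(shap),
               tolerance = 1e-10)
  expect_equal(ex$baseValue + sum(ex$contributions), ex$score,
               tolerance = 1e-10)
})

test_that("a constant model yields zero contributions", {
  ds <- smallDataset(n = 150L, seed = 63L)
  flat <- ds
  flat$label <- rep(c(0, 1), length.out = nrow(flat))
  # a depth-limited tree on pure noise collapses to the root -> constant
  m <- trainFinal(flat, list(algorithm = "dt",
                             params = list(cp = 1, maxdepth = 1L)),
                  seed = 1L)
  s <- scoreVariants(m, flat)
  expect_equal(length(unique(s)), 1L)
  ex <- explainVariant(m, flat[1L, , drop = FALSE], flat[10:20, ],
                       nPerm = 2L, seed = 1L)
  expect_true(all(abs(ex$contributions) < 1e-12))
})
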