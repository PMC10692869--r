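## Rank-statistic AUC-ROC with ties averaged (Mann-Whitney formulation).
#' @keywords internal
.aucRank <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluation metrics for a labeled score set
#'
#' Computes the metric suite used for model selection and reporting. The
#' classification rule is: predict "true variant" iff `score >= threshold`.
#' TPR (sensitivity) is the recall on true variants, TNR (specificity) the
#' recall on false positives, AUC-ROC the rank-based separability of the
#' scores (ties averaged), and MCC the Matthews correlation coefficient in
#' closed form. With single-class labels the AUC and MCC are undefined and
#' returned as `NA`; the confusion counts are always retained.
#'
#' @param labels vector in `{0, 1}` (1 = true variant).
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return named list: `tpr, tnr, auc_roc, mcc, counts` (TP/FN/TN/FP).
#' @export
computeMetrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else NA_real_
  list(tpr = tpr, tnr = tnr, auc_roc = .aucRank(labels, scores), mcc = mcc,
       counts = c(tp = tp, fn = fn, tn = tn, fp = fp))
}
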