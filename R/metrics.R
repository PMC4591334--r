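#' Confusion counts of binary predictions
#'
#' @param predicted,truth equal-length label vectors.
#' @param positive the positive class label (default `"AD"`).
#' @return named integer vector `c(TP, FP, TN, FN)`; the four counts sum to
#'   the number of evaluated samples.
#' @export
confusionCounts <- function(predicted, truth, positive = "AD") {
  if (length(predicted) != length(truth))
    stop("predicted and true label vectors differ in length")
  p <- predicted == positive
  t <- truth == positive
  c(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, and F1 their harmonic
#' mean. Empty denominators are defined as 0 (no positive predictions gives
#' precision 0; no positive truths gives recall 0; F1 is 0 when precision
#' and recall are both 0).
#'
#' @param cc counts as returned by [confusionCounts()].
#' @return named numeric `c(precision, recall, f1)`.
#' @export
precisionRecallF1 <- function(cc) {
  tp <- cc[["TP"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' balanced single-number summary of a binary confusion matrix. Any zero
#' factor in the denominator gives MCC = 0 (the standard convention). MCC is
#' invariant under the simultaneous exchange TP<->TN, FP<->FN.
#'
#' @param cc counts as returned by [confusionCounts()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cc) {
  tp <- as.numeric(cc[["TP"]]); fp <- as.numeric(cc[["FP"]])
  tn <- as.numeric(cc[["TN"]]); fn <- as.numeric(cc[["FN"]])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' The probability that a randomly chosen positive sample outscores a
#' randomly chosen negative one, ties counted one half — identical to the
#' trapezoidal area under the empirical ROC curve and robust to tied
#' confidence scores.
#'
#' @param scores numeric confidence scores (higher = more positive).
#' @param labels class labels; both classes must be present.
#' @param positive the positive class label (default `"AD"`).
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scores, labels, positive = "AD") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires at least one sample of each class")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# internal: full metric set for one evaluation run
.metricSet <- function(scores, truth, positive, threshold = 0.5) {
  predicted <- ifelse(scores >= threshold, positive,
                      setdiff(unique(as.character(truth)), positive)[1])
  cc <- confusionCounts(predicted, truth, positive)
  prf <- precisionRecallF1(cc)
  c(cc, prf, auc = aucScore(scores, truth, positive), mcc = mcc(cc))
}
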