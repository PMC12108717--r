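# Threshold-free and thresholded classification metrics for association
# prediction.  Implemented directly (rank-based AUC, step-wise PR curve,
# confusion tallies) so their semantics are pinned by the package's own
# contracts and cross-checked against brute-force oracles in the tests.

check_scores_labels <- function(scores, labels) {
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("non-finite scores", call. = FALSE)
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  invisible(NULL)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability
#' that a randomly chosen positive outscores a randomly chosen negative,
#' with ties contributing 1/2 (midrank treatment).
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels Binary vector (0/1) of the same length, with at least one
#'   positive and one negative.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1: perfect ranking
#' @export
roc_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) {
    stop("AUC is undefined without both a positive and a negative label",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-wise area with no interpolation: every distinct score is a
#' threshold, tied scores enter as one block, and the area is the sum of
#' `(recall_i - recall_{i-1}) * precision_i` over thresholds in decreasing
#' order.  A constant score vector therefore yields the positive
#' prevalence.
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  npos <- sum(labels == 1)
  if (npos == 0L) {
    stop("AUPR is undefined without a positive label", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  # block ends: last index of each run of tied scores
  ends <- which(c(diff(s) != 0, TRUE))
  prec <- tp[ends] / (tp[ends] + fp[ends])
  rec <- tp[ends] / npos
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Classifies `score >= threshold` as positive and tallies the confusion
#' matrix, reporting sensitivity (= recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/total`, precision `TP/(TP+FP)` and
#' `F1 = 2*Pre*Rec/(Pre+Rec)`.  Any metric whose denominator is zero is
#' reported as 0 and named in the `undefined` field.
#'
#' @inheritParams roc_auc
#' @param threshold Finite classification cutoff.
#' @return A list with `acc`, `sen`, `spe`, `pre`, `f1`, the counts `tp`,
#'   `fp`, `tn`, `fn`, the `threshold`, and `undefined` (character vector
#'   of metrics defaulted to 0).
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  check_scores_labels(scores, labels)
  threshold <- check_scalar_number(threshold, "threshold")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  sen <- safe(tp, tp + fn, "sen")
  spe <- safe(tn, tn + fp, "spe")
  pre <- safe(tp, tp + fp, "pre")
  acc <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- safe(2 * pre * sen, pre + sen, "f1")
  list(acc = acc, sen = sen, spe = spe, pre = pre, f1 = f1,
       tp = tp, fp = fp, tn = tn, fn = fn,
       threshold = threshold, undefined = undefined)
}

#' F1-maximizing classification threshold
#'
#' Scans every distinct score (in decreasing order) as a candidate cutoff
#' and returns the one maximizing F1; among ties the highest threshold
#' wins, keeping the choice deterministic.
#'
#' @inheritParams roc_auc
#' @return A list with `threshold` and the attained `f1`.
#' @export
best_f1_threshold <- function(scores, labels) {
  check_scores_labels(scores, labels)
  npos <- sum(labels == 1)
  if (npos == 0L) {
    stop("F1 is undefined without a positive label", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  ends <- which(c(diff(s) != 0, TRUE))
  pre <- tp[ends] / (tp[ends] + fp[ends])
  rec <- tp[ends] / npos
  denom <- pre + rec
  f1 <- ifelse(denom == 0, 0, 2 * pre * rec / denom)
  best <- which.max(f1)   # first maximum = highest threshold
  list(threshold = s[ends[best]], f1 = f1[best])
}
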