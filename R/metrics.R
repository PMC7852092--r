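# The four challenge metrics (auROC, auPRC, recall at 50%/10% FDR) and the
# rank-based unified score.

#' Bundle scores and binary labels for evaluation
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or logical) labels of the same length. Ambiguous
#'   bins must be excluded before construction.
#' @param bins Optional matching bin data.frame.
#' @return A list of class `"scored_labels"`.
#' @export
scored_labels <- function(scores, labels, bins = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  structure(list(scores = as.numeric(scores), labels = labels, bins = bins),
            class = "scored_labels")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive
#' outscores a random negative, with ties counted one half (equivalent to
#' the trapezoidal area over all distinct thresholds).
#'
#' @param sl A [scored_labels()] object.
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(sl) {
  pos <- sl$scores[sl$labels == 1L]
  neg <- sl$scores[sl$labels == 0L]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("auROC undefined: both classes must be present")
  }
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

pr_points <- function(sl) {
  ord <- order(sl$scores, decreasing = TRUE)
  y <- sl$labels[ord]
  s <- sl$scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each threshold
  n_pos <- sum(y)
  list(recall = tp[keep] / n_pos,
       precision = tp[keep] / (tp[keep] + fp[keep]))
}

#' Area under the precision-recall curve
#'
#' Interpolation-free step summation `sum((R_k - R_{k-1}) * P_k)` over
#' descending score thresholds.
#'
#' @param sl A [scored_labels()] object.
#' @return auPRC in `(0, 1]`.
#' @export
auprc <- function(sl) {
  if (sum(sl$labels) == 0) stop("auPRC undefined: no positive labels")
  pr <- pr_points(sl)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' Maximum recall at a bounded false-discovery rate
#'
#' The largest recall over all score thresholds whose precision is at
#' least `1 - fdr`; 0 if no threshold qualifies.
#'
#' @param sl A [scored_labels()] object.
#' @param fdr Allowed FDR in (0, 1).
#' @return Recall in `[0, 1]`.
#' @export
recall_at_fdr <- function(sl, fdr) {
  stopifnot(fdr > 0, fdr < 1)
  if (sum(sl$labels) == 0) return(0)
  pr <- pr_points(sl)
  ok <- pr$precision >= 1 - fdr
  if (!any(ok)) 0 else max(pr$recall[ok])
}

#' Rank-based unified score
#'
#' `sum(log(r / 6))` over the four measure ranks (1 = best); smaller is
#' better, and a method ranked 6 on every measure scores 0.
#'
#' @param ranks Numeric vector of 4 ranks (>= 1).
#' @return The unified score.
#' @export
unified_score <- function(ranks) {
  stopifnot(length(ranks) == 4, all(ranks >= 1))
  sum(log(ranks / 6))
}

#' Per-measure rank fraction
#'
#' The companion convention `mean(r / 6)`, matching the scale of published
#' per-target comparison tables.
#'
#' @param ranks Numeric vector of 4 ranks (>= 1).
#' @return Mean of `r / 6` over the measures.
#' @export
rank_fraction <- function(ranks) {
  stopifnot(length(ranks) == 4, all(ranks >= 1))
  mean(ranks / 6)
}

#' Evaluate all four challenge metrics at once
#'
#' @param sl A [scored_labels()] object.
#' @return Named vector: `auroc`, `auprc`, `recall_at_50_fdr`,
#'   `recall_at_10_fdr`.
#' @export
challenge_metrics <- function(sl) {
  c(auroc = auroc(sl), auprc = auprc(sl),
    recall_at_50_fdr = recall_at_fdr(sl, 0.5),
    recall_at_10_fdr = recall_at_fdr(sl, 0.1))
}

#' Rank methods per measure (average ranks on ties)
#'
#' @param metric_matrix Methods x measures matrix of metric values
#'   (larger = better).
#' @return Matrix of the same shape holding per-measure ranks (1 = best).
#' @export
rank_methods <- function(metric_matrix) {
  apply(metric_matrix, 2, function(v) rank(-v, ties.method = "average"))
}

#' Prior-correct prediction scores after rebalanced training
#'
#' Training with `negative_ratio` resampled negatives per positive shifts
#' the model's operating prior away from the balanced one, so a fixed 0.5
#' positive-call threshold no longer means "more likely bound than not".
#' The standard logit correction for class rebalancing restores the
#' balanced calibration: `sigmoid(logit(s) + log(negative_ratio))`. With
#' the balanced default ratio of 1 this is the identity; the correction is
#' monotone, so ranking metrics (auROC, auPRC, recall at FDR) are
#' unaffected.
#'
#' @param scores Raw merged scores in (0, 1).
#' @param negative_ratio The `negative_ratio` the model was trained with.
#' @return Calibrated scores in (0, 1).
#' @export
calibrate_scores <- function(scores, negative_ratio) {
  s <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  stats::plogis(stats::qlogis(s) + log(negative_ratio))
}
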