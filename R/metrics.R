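#' ROC curve by threshold sweep
#'
#' Sweeps the distinct score values in descending order; tied scores
#' collapse to a single point. The endpoints (0,0) and (1,1) are always
#' included. Both classes must be present.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels aligned with `scores`.
#' @return A tibble of class `asm_roc` with columns `fpr`, `tpr` (both
#'   nondecreasing) and attributes `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  check_scored_labels(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  # indices of the last element of each tied block in the descending sweep
  block_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[block_end]
  fp <- (block_end) - tp
  pts <- tibble(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- dplyr::bind_rows(pts, tibble(fpr = 1, tpr = 1))
  pts <- dplyr::distinct(pts)
  structure(pts, class = c("asm_roc", class(pts)), n_pos = n_pos, n_neg = n_neg)
}

check_scored_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("`scores` and `labels` lengths differ")
  if (length(scores) == 0) abort("empty score set")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    abort("both classes must be present")
  if (any(!is.finite(scores))) abort("scores must be finite")
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under an [roc_curve()] (equivalently, the
#' Mann-Whitney U statistic with ties counted half).
#'
#' @param x An `asm_roc` curve, or numeric scores (then `labels` required).
#' @param labels 0/1 labels when `x` is a score vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(x, labels = NULL) {
  curve <- if (inherits(x, "asm_roc")) x else roc_curve(x, labels)
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

#' Recall at a fixed false-positive rate
#'
#' Reads the true-positive rate off the ROC staircase at `fpr_target` by
#' linear interpolation. When the target coincides with an FPR at which the
#' curve is vertical, the maximum TPR at that FPR is returned (optimistic
#' convention). Between two attained FPRs the interpolation runs along the
#' actual staircase segment, i.e. from the top of the vertical at the left
#' FPR to the bottom of the vertical at the right FPR.
#'
#' @param curve An `asm_roc` from [roc_curve()].
#' @param fpr_target One or more target FPRs in `[0, 1]`.
#' @return Numeric vector of interpolated recalls.
#' @examples
#' rc <- roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
#' recall_at_fpr(rc, 0.25)  # 0.5
#' @export
recall_at_fpr <- function(curve, fpr_target) {
  stopifnot(inherits(curve, "asm_roc"))
  if (any(fpr_target < 0 | fpr_target > 1)) abort("`fpr_target` must be in [0, 1]")
  vapply(fpr_target, function(t) {
    exact <- curve$fpr == t
    if (any(exact)) return(max(curve$tpr[exact]))
    left <- max(which(curve$fpr < t))
    right <- min(which(curve$fpr > t))
    x0 <- curve$fpr[left]; x1 <- curve$fpr[right]
    y0 <- max(curve$tpr[curve$fpr == x0])   # top of left vertical
    y1 <- min(curve$tpr[curve$fpr == x1])   # bottom of right vertical
    y0 + (t - x0) / (x1 - x0) * (y1 - y0)
  }, numeric(1))
}

#' Average precision
#'
#' Step-function (non-interpolated) average precision over the
#' descending-score sweep, the standard retrieval definition:
#' \eqn{\sum_i (R_i - R_{i-1}) P_i}. Tied scores are grouped into one
#' operating point.
#'
#' @inheritParams roc_curve
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  check_scored_labels(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y == 1)
  block_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[block_end]
  n <- block_end
  prec <- tp / n
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Precision/recall/F1 against an evidenced motif set
#'
#' Proteome-scan accounting: of `n_hits` sequences above a threshold,
#' `n_true_hits` carry an independently evidenced motif, out of
#' `n_evidenced` evidenced motifs in total. Recall = true hits / evidenced,
#' precision = true hits / hits (0 when there are no hits), F1 = harmonic
#' mean of the unrounded precision and recall (0 when both are 0).
#'
#' @param n_true_hits,n_hits,n_evidenced Nonnegative counts with
#'   `n_true_hits <= min(n_hits, n_evidenced)` and `n_evidenced >= 1`.
#' @param threshold Optional threshold to record alongside the counts.
#' @return One-row tibble with unrounded `precision`, `recall`, `f1` and
#'   2-decimal `precision_2dp`, `recall_2dp`, `f1_2dp` (table style).
#' @examples
#' prf_vs_evidenced(16, 124, 25)
#' @export
prf_vs_evidenced <- function(n_true_hits, n_hits, n_evidenced, threshold = NA_real_) {
  if (n_evidenced < 1) abort("`n_evidenced` must be >= 1")
  if (n_true_hits < 0 || n_hits < 0) abort("counts must be nonnegative")
  if (n_true_hits > n_hits) abort("`n_true_hits` cannot exceed `n_hits`")
  if (n_true_hits > n_evidenced) abort("`n_true_hits` cannot exceed `n_evidenced`")
  precision <- if (n_hits == 0) 0 else n_true_hits / n_hits
  recall <- n_true_hits / n_evidenced
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(
    threshold = threshold,
    n_hits = as.integer(n_hits), n_true_hits = as.integer(n_true_hits),
    n_evidenced = as.integer(n_evidenced),
    precision = precision, recall = recall, f1 = f1,
    precision_2dp = round(precision, 2), recall_2dp = round(recall, 2),
    f1_2dp = round(f1, 2)
  )
}

#' Retention rate of a score set
#'
#' Fraction of sequences scored at or above the detection threshold
#' ("detected").
#'
#' @param scores Numeric scores.
#' @param threshold Detection threshold (default 0.5).
#' @return Fraction in `[0, 1]`.
#' @export
retention_rate <- function(scores, threshold = 0.5) {
  if (length(scores) == 0) abort("empty score set")
  mean(scores >= threshold)
}

#' @describeIn roc_curve ROC plot on log-scaled FPR (the convention for
#'   highly imbalanced motif retrieval).
#' @param object An `asm_roc`.
#' @param ... Unused.
#' @export
autoplot.asm_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "recall") +
    ggplot2::theme_minimal()
}

#' Evaluate positive vs negative scores
#'
#' One-stop summary for imbalanced motif retrieval: AP, AUROC, and
#' interpolated recall at each requested FPR.
#'
#' @param pos_scores,neg_scores Numeric score vectors for the positive and
#'   negative sets.
#' @param fpr_targets FPRs at which to report recall
#'   (default `10^-(1:5)`).
#' @return A one-row tibble: `n_pos`, `n_neg`, `ap`, `auroc`, and one
#'   `recall_at_<fpr>` column per target.
#' @export
evaluate_scores <- function(pos_scores, neg_scores, fpr_targets = 10^-(1:5)) {
  scores <- c(pos_scores, neg_scores)
  labels <- c(rep(1, length(pos_scores)), rep(0, length(neg_scores)))
  curve <- roc_curve(scores, labels)
  rc <- recall_at_fpr(curve, fpr_targets)
  out <- tibble(
    n_pos = length(pos_scores), n_neg = length(neg_scores),
    ap = average_precision(scores, labels), auroc = auroc(curve)
  )
  rc_tbl <- as_tibble(as.list(setNames(rc, paste0("recall_at_", format(fpr_targets,
                                                                       scientific = TRUE,
                                                                       trim = TRUE)))))
  dplyr::bind_cols(out, rc_tbl)
}
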