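# ROC curve, AUC with a DeLong confidence interval, and the Youden-index
# operating point. The AUC is the tie-corrected Mann-Whitney statistic
# U / (n1 * n0): the probability that a random case outscores a random
# control, with half credit for ties.

#' ROC curve and AUC with DeLong confidence interval
#'
#' Computes ROC points at every distinct score threshold (prediction positive
#' when score >= threshold), the Mann-Whitney AUC with tie correction, a
#' confidence interval from DeLong's placement-variance estimator, and the
#' operating point maximizing Youden's J = sensitivity + specificity - 1
#' (ties broken toward the highest threshold).
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (1 = case), both classes present.
#' @param ci_level confidence level for the AUC interval (default 0.95).
#' @return object of class `aki_roc`: `auc`, `auc_ci`, `points` (data.frame
#'   `threshold`, `fpr`, `tpr`), `threshold`, `sensitivity`, `specificity`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, ci_level = 0.95) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_akiphen("labels", "labels must be 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_akiphen("labels", "both classes must be present")
  if (length(scores) != length(labels)) stop_akiphen("labels", "scores/labels length mismatch")

  degenerate <- length(unique(scores)) == 1L
  if (degenerate) {
    warn_akiphen("degenerate_roc", "all scores identical; ROC is the diagonal, AUC = 0.5")
  }

  # Mann-Whitney AUC via mid-ranks (half credit for ties)
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong placements
  xs <- scores[labels == 1L]
  ys <- scores[labels == 0L]
  v10 <- vapply(xs, function(xi) (sum(ys < xi) + 0.5 * sum(ys == xi)) / n0, 0)
  v01 <- vapply(ys, function(yj) (sum(xs > yj) + 0.5 * sum(xs == yj)) / n1, 0)
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  if (!is.finite(var_auc)) var_auc <- 0
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- c(
    max(0, auc - zq * sqrt(var_auc)),
    min(1, auc + zq * sqrt(var_auc))
  )

  # ROC points at each distinct threshold, descending
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  pos_cum <- cumsum(labels[ord] == 1L)
  neg_cum <- cumsum(labels[ord] == 0L)
  last_at_thr <- cumsum(as.integer(table(factor(s_sorted, levels = thr))))
  tpr <- pos_cum[last_at_thr] / n1
  fpr <- neg_cum[last_at_thr] / n0
  points <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )

  j <- points$tpr - points$fpr
  best <- which.max(j) # first (highest threshold) among ties
  structure(
    list(
      auc = auc, auc_ci = ci, var_auc = var_auc, points = points,
      threshold = points$threshold[best],
      sensitivity = points$tpr[best],
      specificity = 1 - points$fpr[best],
      n_pos = n1, n_neg = n0, ci_level = ci_level,
      degenerate = degenerate
    ),
    class = "aki_roc"
  )
}

#' @export
print.aki_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (%.0f%% CI %.3f-%.3f), n = %d cases / %d controls\n",
    x$auc, 100 * x$ci_level, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg
  ))
  cat(sprintf(
    "Youden operating point: threshold %.4g, sensitivity %.1f%%, specificity %.1f%%\n",
    x$threshold, 100 * x$sensitivity, 100 * x$specificity
  ))
  invisible(x)
}
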