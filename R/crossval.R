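# Stratified k-fold cross-validation with out-of-fold scoring.

# Evaluate an expression under a local RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_rng_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Seeded stratified fold assignment
#'
#' Partitions indices into `k` folds stratified by the binary outcome: within
#' each class, a seeded random permutation is dealt round-robin, so per-fold
#' class counts differ by at most one from proportionality.
#'
#' @param y binary outcome vector.
#' @param k number of folds.
#' @param seed RNG seed for the permutation.
#' @return integer vector of fold labels in 1..k, aligned with `y`.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  n <- length(y)
  if (n < k) stop_akiphen("folds", "need at least k observations for k folds")
  folds <- integer(n)
  with_rng_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Out-of-fold logistic scores by stratified k-fold cross-validation
#'
#' Splits patients into `config$n_folds` seeded, outcome-stratified folds;
#' each patient receives the predicted AKI probability from the model fitted
#' on the other folds, so no patient is scored by a model trained on them.
#' Deterministic given `config$rng_seed`.
#'
#' @param x predictor matrix (no intercept column).
#' @param y binary outcome.
#' @param config an [analysis_config()].
#' @return numeric vector of out-of-fold probabilities aligned with `y`, with
#'   attribute `"folds"` (the fold assignment).
#' @export
cross_validated_scores <- function(x, y, config = analysis_config()) {
  if (is.data.frame(x)) x <- as.matrix(x)
  y <- as.integer(y)
  k <- config$n_folds
  folds <- stratified_folds(y, k, config$rng_seed)
  for (f in seq_len(k)) {
    if (length(unique(y[folds != f])) < 2L) {
      stop_akiphen("fold_class", sprintf(
        "training data for fold %d contains a single class; use fewer folds", f
      ))
    }
  }
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_logistic(x[!test, , drop = FALSE], y[!test], config)
    scores[test] <- predict(fit, x[test, , drop = FALSE])
  }
  attr(scores, "folds") <- folds
  scores
}
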