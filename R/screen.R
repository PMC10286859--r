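# Univariate association screening: Pearson chi-squared for categorical
# variables, Wilcoxon rank-sum for continuous ones, with the p < alpha gate
# that selects variables for the multivariate model.

#' Pearson chi-squared test on a contingency table
#'
#' Computes the uncorrected Pearson statistic sum((O - E)^2 / E) with expected
#' counts from the margin products, df = (r - 1)(c - 1), and the upper-tail
#' chi-squared p-value. No continuity correction is applied, matching the
#' screening convention used throughout.
#'
#' @param counts r x c matrix of nonnegative integer counts, r, c >= 2.
#' @return list with `statistic`, `df`, `p_value` and `expected`.
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop_akiphen("table_shape", "contingency table must be at least 2 x 2")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_akiphen("table_counts", "contingency table must contain nonnegative integers")
  }
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    deg <- c(
      if (any(rs == 0)) paste0("row ", which(rs == 0)),
      if (any(cs == 0)) paste0("column ", which(cs == 0))
    )
    stop_akiphen("zero_margin", sprintf(
      "degenerate contingency table: empty %s", paste(deg, collapse = ", ")
    ))
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    expected = ht$expected
  )
}

#' Wilcoxon rank-sum test for two samples
#'
#' Mid-ranks are used for ties. The p-value is exact (null permutation
#' distribution) when both samples are small and tie-free, otherwise a normal
#' approximation with tie-corrected variance and continuity correction, the
#' same convention as [stats::wilcox.test()]. The reported `rank_sum` is the
#' sum of pooled ranks of `x`; `z` is the tie- and continuity-corrected
#' standardized Mann-Whitney statistic.
#'
#' @param x,y numeric samples, both nonempty.
#' @return list with `rank_sum`, `u`, `z` and `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop_akiphen("empty_sample", "both samples must be nonempty")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  rank_sum <- sum(r[seq_len(n1)])
  u <- rank_sum - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1)))
  d <- u - mu
  z <- if (sigma2 > 0) (d - sign(d) * 0.5) / sqrt(sigma2) else 0
  if (d == 0) z <- 0
  p <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE)$p.value)
  list(rank_sum = rank_sum, u = u, z = z, p_value = p)
}

#' Univariate screen over a set of candidate variables
#'
#' Runs a Pearson chi-squared test (categorical variables, cross-tabulated
#' against the AKI label) or a Wilcoxon rank-sum test (continuous variables,
#' AKI vs non-AKI samples) for each variable and flags those with
#' p < `alpha` for inclusion in the multivariate model. A variable constant
#' across all patients yields `selected = FALSE` with a warning, not an error.
#'
#' @param data data.frame of covariates, one row per patient.
#' @param labels binary AKI outcome (0/1 or logical), aligned with `data` rows.
#' @param variables data.frame with columns `variable` (names in `data`) and
#'   `type` (`"categorical"` or `"continuous"`). Defaults to treating the
#'   known flag columns as categorical and lab columns as continuous.
#' @param alpha selection threshold on the raw p-value (default 0.05).
#' @param p_adjust `"none"` (default, the faithful raw-p gate) or `"BH"` for
#'   a Benjamini-Hochberg adjusted gate.
#' @return data.frame with one row per variable in input order: `variable`,
#'   `test`, `statistic`, `df`, `p_value`, `selected`.
#' @export
screen <- function(data, labels, variables = NULL, alpha = 0.05,
                   p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop_akiphen("labels", "labels must be binary with no missing values")
  }
  if (length(labels) != nrow(data)) {
    stop_akiphen("labels", "labels must align with data rows")
  }
  if (is.null(variables)) {
    variables <- default_variable_spec(data)
  }
  if (!all(variables$type %in% c("categorical", "continuous"))) {
    stop_akiphen("variable_type", "variable type must be categorical or continuous")
  }
  missing_vars <- setdiff(variables$variable, names(data))
  if (length(missing_vars)) {
    stop_akiphen("missing_column", sprintf(
      "variables not present in data: %s", paste(missing_vars, collapse = ", ")
    ))
  }
  rows <- lapply(seq_len(nrow(variables)), function(k) {
    v <- variables$variable[k]
    type <- variables$type[k]
    x <- data[[v]]
    out <- data.frame(
      variable = v, test = if (type == "categorical") "chi2" else "wilcoxon",
      statistic = NA_real_, df = NA_real_, p_value = NA_real_,
      selected = FALSE, stringsAsFactors = FALSE
    )
    if (length(unique(x[!is.na(x)])) < 2L) {
      warn_akiphen("constant_variable", sprintf(
        "variable '%s' is constant across patients; not selected", v
      ))
      return(out)
    }
    if (type == "categorical") {
      tab <- table(factor(labels, levels = c(1L, 0L)), x)
      res <- pearson_chi2(unclass(tab))
      out$statistic <- res$statistic
      out$df <- res$df
      out$p_value <- res$p_value
    } else {
      res <- wilcoxon_rank_sum(x[labels == 1L], x[labels == 0L])
      out$statistic <- res$rank_sum
      out$p_value <- res$p_value
    }
    out
  })
  res <- do.call(rbind, rows)
  gate_p <- if (p_adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  res$selected <- !is.na(gate_p) & gate_p < alpha
  rownames(res) <- NULL
  res
}

default_variable_spec <- function(data) {
  flags <- intersect(covariate_flags(), names(data))
  labs <- intersect(covariate_labs(), names(data))
  data.frame(
    variable = c(flags, labs),
    type = c(rep("categorical", length(flags)), rep("continuous", length(labs))),
    stringsAsFactors = FALSE
  )
}
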