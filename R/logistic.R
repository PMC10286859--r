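# Multivariate logistic regression by maximum likelihood (IRLS / Newton-
# Raphson on the Bernoulli log-likelihood), with Wald odds ratios and
# confidence intervals. Standard errors come from the inverse observed
# information at the optimum.

#' Analysis configuration
#'
#' @param alpha significance threshold (default 0.05).
#' @param ci_level confidence level for ORs and the AUC (default 0.95).
#' @param n_folds cross-validation folds (default 10).
#' @param rng_seed seed for the fold partition.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum IRLS iterations.
#' @param imbalance_handling `"none"` (unweighted ML, default) or
#'   `"class_weights"` (inverse-prevalence weights).
#' @param standardize standardize continuous predictors before fitting
#'   (default `FALSE`: per-unit odds ratios).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, ci_level = 0.95, n_folds = 10,
                            rng_seed = 1L, tol = 1e-8, max_iter = 50L,
                            imbalance_handling = c("none", "class_weights"),
                            standardize = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, ci_level > 0, ci_level < 1, n_folds >= 2)
  structure(
    list(
      alpha = alpha, ci_level = ci_level, n_folds = as.integer(n_folds),
      rng_seed = as.integer(rng_seed), tol = tol, max_iter = as.integer(max_iter),
      imbalance_handling = match.arg(imbalance_handling),
      standardize = standardize
    ),
    class = "analysis_config"
  )
}

# Build the design matrix (with intercept) from a covariate data.frame.
build_design <- function(data, variables, outcome, standardize = FALSE) {
  x <- as.matrix(data[, variables, drop = FALSE])
  if (anyNA(x)) stop_akiphen("missing_cells", "design matrix contains missing values")
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L))) stop_akiphen("labels", "outcome must be binary")
  if (length(unique(y)) < 2L) stop_akiphen("labels", "outcome must contain both classes")
  if (nrow(x) <= ncol(x) + 1L) stop_akiphen("design", "need n > p")
  if (standardize) {
    cont <- apply(x, 2, function(col) length(unique(col)) > 2L)
    x[, cont] <- scale(x[, cont, drop = FALSE])
  }
  list(x = cbind(`(Intercept)` = 1, x), y = y)
}

#' Fit a logistic regression by IRLS maximum likelihood
#'
#' Newton-Raphson on the Bernoulli log-likelihood, declared converged when
#' the log-likelihood change falls below `config$tol`. Separation (a
#' coefficient diverging beyond a bound) and non-convergence raise typed
#' errors rather than returning an unreliable fit.
#'
#' @param x numeric predictor matrix (n x p, no intercept column) or a
#'   data.frame of numeric columns.
#' @param y binary outcome vector (0/1), both classes present.
#' @param config an [analysis_config()].
#' @param weights optional nonnegative case weights.
#' @return object of class `aki_logistic`: coefficients (with intercept),
#'   `se`, `wald` ((beta/se)^2), `or`, `ci_low`/`ci_high`, `p_value`,
#'   `loglik`, `converged`, `iterations`, `vcov`.
#' @export
fit_logistic <- function(x, y, config = analysis_config(), weights = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyNA(x) || anyNA(y)) stop_akiphen("missing_cells", "no missing values allowed")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L) {
    stop_akiphen("labels", "outcome must be binary with both classes present")
  }
  if (nrow(x) != length(y)) stop_akiphen("design", "x rows must match length(y)")
  if (nrow(x) <= ncol(x) + 1L) stop_akiphen("design", "need n > p")
  X <- cbind(`(Intercept)` = 1, x)
  n <- nrow(X)
  p <- ncol(X)
  w0 <- if (is.null(weights)) rep(1, n) else weights
  if (config$imbalance_handling == "class_weights" && is.null(weights)) {
    w0 <- ifelse(y == 1L, n / (2 * sum(y == 1L)), n / (2 * sum(y == 0L)))
  }

  beta <- numeric(p)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  bound <- 30
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    ll <- sum(w0 * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300))))
    trace <- c(trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < config$tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- w0 * mu * (1 - mu)
    info <- crossprod(X, X * w)
    score <- crossprod(X, w0 * (y - mu))
    step <- tryCatch(solve(info, score), error = function(e) {
      stop_akiphen("separation", paste(
        "information matrix is singular; predictors may be collinear or the",
        "classes separated - consider removing a variable"
      ))
    })
    beta <- beta + drop(step)
    if (max(abs(beta)) > bound) {
      stop_akiphen("separation", sprintf(
        paste(
          "apparent complete or quasi-complete separation: |beta| exceeded %g",
          "for '%s' - consider removing that variable"
        ),
        bound, colnames(X)[which.max(abs(beta))]
      ))
    }
    if (iter >= config$max_iter) break
  }
  if (!converged) {
    stop_akiphen(
      "nonconvergence",
      sprintf(
        "IRLS did not converge in %d iterations (log-likelihood trace: %s)",
        config$max_iter, paste(sprintf("%.4f", utils::tail(trace, 5)), collapse = ", ")
      ),
      trace = trace
    )
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- w0 * mu * (1 - mu)
  vcov <- solve(crossprod(X, X * w))
  se <- sqrt(diag(vcov))
  zq <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  wald <- (beta / se)^2
  structure(
    list(
      coefficients = stats::setNames(beta, colnames(X)),
      se = stats::setNames(se, colnames(X)),
      wald = stats::setNames(wald, colnames(X)),
      or = exp(beta),
      ci_low = exp(beta - zq * se),
      ci_high = exp(beta + zq * se),
      p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
      loglik = trace[length(trace)],
      converged = converged,
      iterations = iter,
      vcov = vcov,
      ci_level = config$ci_level
    ),
    class = "aki_logistic"
  )
}

#' Predict event probabilities from a logistic fit
#' @param object an `aki_logistic` fit.
#' @param newdata matrix or data.frame with the fit's predictor columns.
#' @param ... unused.
#' @export
predict.aki_logistic <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  X <- cbind(1, newdata[, names(object$coefficients)[-1], drop = FALSE])
  stats::plogis(drop(X %*% object$coefficients))
}

#' Wald summary table for a logistic fit
#'
#' One row per coefficient in design order: beta, standard error, Wald
#' statistic (beta/se)^2, odds ratio exp(beta) with its confidence interval
#' exp(beta +/- z * se), and the chi-squared p-value.
#'
#' @param fit a converged `aki_logistic`.
#' @param include_intercept keep the intercept row (default `FALSE`).
#' @return data.frame with columns `variable`, `beta`, `se`, `wald`, `or`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
wald_table <- function(fit, include_intercept = FALSE) {
  stopifnot(inherits(fit, "aki_logistic"), isTRUE(fit$converged))
  out <- data.frame(
    variable = names(fit$coefficients),
    beta = unname(fit$coefficients),
    se = unname(fit$se),
    wald = unname(fit$wald),
    or = unname(fit$or),
    ci_low = unname(fit$ci_low),
    ci_high = unname(fit$ci_high),
    p_value = unname(fit$p_value),
    stringsAsFactors = FALSE
  )
  if (!include_intercept) out <- out[out$variable != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.aki_logistic <- function(x, ...) {
  cat(sprintf(
    "logistic fit: %d coefficients, loglik %.3f, %d iterations\n",
    length(x$coefficients), x$loglik, x$iterations
  ))
  print(wald_table(x, include_intercept = TRUE), digits = 3)
  invisible(x)
}
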