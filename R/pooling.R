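# Rubin's Rules: combine M per-imputation estimates and variances into a
# pooled estimate, total variance, degrees of freedom and interval.

#' Pool estimates across imputations by Rubin's Rules
#'
#' Given M completed-data estimates and their variances, the pooled estimate
#' is their mean, the within-imputation variance `W` is the mean variance,
#' the between-imputation variance `B` is the sample variance (divisor
#' `M - 1`) of the estimates, and the total variance is
#' `W + (1 + 1/M) * B`.  The degrees of freedom follow the classic 1987
#' formula `(M - 1) * (1 + W / ((1 + 1/M) * B))^2`, infinite when `B = 0`;
#' the interval is `estimate +/- t_{df} * sqrt(total)`.
#'
#' @param estimates numeric vector of M per-imputation estimates (M >= 2).
#' @param variances numeric vector of M per-imputation variances (>= 0).
#' @param conf_level confidence level for the pooled interval.
#' @return an object of class `pooled_result` with elements `estimate`,
#'   `within_var`, `between_var`, `total_var`, `df`, `ci_low`, `ci_high`,
#'   `M`.
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  M <- length(estimates)
  if (M < 2) stop("Rubin's Rules require M >= 2 imputations")
  stopifnot(length(variances) == M, all(is.finite(estimates)),
            all(is.finite(variances)), all(variances >= 0))
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  total <- W + (1 + 1 / M) * B
  df <- if (B == 0) Inf else (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
  crit <- qt(1 - (1 - conf_level) / 2, df)
  structure(list(estimate = qbar, within_var = W, between_var = B,
                 total_var = total, df = df,
                 ci_low = qbar - crit * sqrt(total),
                 ci_high = qbar + crit * sqrt(total),
                 M = M, conf_level = conf_level),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf(
    "Rubin-pooled estimate %.4f (total var %.4g = within %.4g + (1+1/%d)*between %.4g)\n",
    x$estimate, x$total_var, x$within_var, x$M, x$between_var))
  cat(sprintf("  df = %.2f, %d%% CI [%.4f, %.4f]\n", x$df,
              round(100 * x$conf_level), x$ci_low, x$ci_high))
  invisible(x)
}

#' Pool the target coefficient of a list of analysis fits
#'
#' Convenience wrapper extracting the target term's estimate and variance
#' from each per-imputation [fit_quadratic_ols()] /
#' [fit_interaction_ols()] / [fit_logistic_quadratic()] result and applying
#' [pool_rubin()].
#'
#' @param fits list of `analysis_fit` objects (all converged).
#' @param conf_level confidence level.
#' @return a `pooled_result`.
#' @export
pool_fits <- function(fits, conf_level = 0.95) {
  if (any(!vapply(fits, `[[`, TRUE, "converged")))
    stop("cannot pool: some per-imputation fits did not converge")
  ests <- vapply(fits, function(f) f$coefficients[[f$term_index]], 0)
  vars <- vapply(fits, function(f) f$covariance[f$term_index, f$term_index], 0)
  pool_rubin(ests, vars, conf_level)
}
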