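# Analysis models: OLS with a quadratic or interaction term, logistic
# regression with a quadratic term, and the complete-data / complete-case
# reference estimators.  The derived term is always supplied as its own
# column because JAV-imputed derived values need not equal the transform of
# the imputed X.

fit_ols <- function(y, U, term_index) {
  n <- length(y)
  p <- ncol(U)
  if (n <= p) stop("need more rows than coefficients")
  qrU <- qr(U)
  if (qrU$rank < p) stop("singular design matrix")
  coefs <- qr.coef(qrU, y)
  res <- y - drop(U %*% coefs)
  df <- n - p
  sigma2 <- sum(res^2) / df
  covmat <- sigma2 * chol2inv(qr.R(qrU))
  dimnames(covmat) <- list(colnames(U), colnames(U))
  structure(list(coefficients = coefs, covariance = covmat,
                 residual_df = df, term_index = term_index,
                 kind = "ols", converged = TRUE),
            class = "analysis_fit")
}

#' Ordinary least squares with a quadratic term
#'
#' Fits `Y ~ 1 + X + derived` by least squares with the classical covariance
#' `sigma2_hat * (U'U)^{-1}` (residual df `n - 3`).  `derived` defaults to
#' `x^2` but is a free column so that JAV-completed data can be analysed.
#'
#' @param y outcome vector.
#' @param x covariate vector.
#' @param derived quadratic-term column, by default `x^2`.
#' @return an object of class `analysis_fit`; the quadratic coefficient is
#'   `coefficients[term_index]`.
#' @export
fit_quadratic_ols <- function(y, x, derived = x^2) {
  fit_ols(y, cbind("(Intercept)" = 1, x = x, xsq = derived), 3L)
}

#' Ordinary least squares with an interaction term
#'
#' Fits `Y ~ 1 + X + Z + derived` with `derived` the interaction column
#' (default `x * z`); the interaction coefficient is the target term.
#'
#' @param y,x,z outcome and covariates.
#' @param derived interaction-term column, by default `x * z`.
#' @return an `analysis_fit` with `term_index = 4`.
#' @export
fit_interaction_ols <- function(y, x, z, derived = x * z) {
  fit_ols(y, cbind("(Intercept)" = 1, x = x, z = z, xz = derived), 4L)
}

#' Logistic regression with a quadratic term
#'
#' Maximum-likelihood fit of `logit P(Y = 1) = b0 + b1*X + b2*derived` by
#' iteratively reweighted least squares (tolerance 1e-8, at most 100
#' iterations), with covariance the inverse observed information.  The
#' coefficients are unconstrained even though the generating model ties the
#' linear and quadratic coefficients.  Non-convergence, rank deficiency, a
#' degenerate outcome, or a non-finite information matrix are flagged via
#' `converged = FALSE` rather than raising an error, so simulation
#' replicates can be excluded and counted.
#'
#' @param y binary (0/1) outcome vector.
#' @param x covariate vector.
#' @param derived quadratic-term column, by default `x^2`.
#' @return an `analysis_fit` with `kind = "logistic"`.
#' @export
fit_logistic_quadratic <- function(y, x, derived = x^2) {
  stopifnot(all(y %in% c(0, 1)))
  failed_fit <- function() {
    structure(list(coefficients = rep(NA_real_, 3L),
                   covariance = matrix(NA_real_, 3L, 3L),
                   residual_df = NA_integer_, term_index = 3L,
                   kind = "logistic", converged = FALSE),
              class = "analysis_fit")
  }
  if (length(unique(y)) < 2L) return(failed_fit())
  U <- cbind("(Intercept)" = 1, x = x, xsq = derived)
  fit <- tryCatch(
    suppressWarnings(glm.fit(U, y, family = binomial(),
                             control = list(epsilon = 1e-8, maxit = 100L))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$rank < 3L ||
      any(!is.finite(fit$coefficients)))
    return(failed_fit())
  info <- crossprod(U * sqrt(fit$weights))
  covmat <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(covmat) || any(!is.finite(covmat))) return(failed_fit())
  dimnames(covmat) <- list(colnames(U), colnames(U))
  structure(list(coefficients = fit$coefficients, covariance = covmat,
                 residual_df = NA_integer_, term_index = 3L,
                 kind = "logistic", converged = TRUE),
            class = "analysis_fit")
}

#' Reference estimators: complete-data and complete-case
#'
#' The complete-data ("cdata") analysis fits the analysis model on all n
#' rows using the pre-deletion covariate (`x_true`, simulation context
#' only); the complete-case ("ccase") analysis uses only rows with `r = 1`.
#'
#' @param data an [incomplete_dataset()].
#' @param which `"cdata"` or `"ccase"`.
#' @param analysis `"quadratic"`, `"quadratic_centered"`, `"interaction"`
#'   or `"logistic"`.
#' @return an `analysis_fit`.
#' @export
estimate_reference <- function(data, which = c("cdata", "ccase"),
                               analysis = c("quadratic", "quadratic_centered",
                                            "interaction", "logistic")) {
  which <- match.arg(which)
  analysis <- match.arg(analysis)
  if (which == "cdata") {
    if (is.null(data$x_true))
      stop("complete-data analysis requires x_true (pre-deletion values)")
    idx <- seq_len(data$n)
    x <- data$x_true
  } else {
    idx <- which(data$r == 1L)
    x <- data$x
  }
  y <- data$y[idx]
  x <- x[idx]
  switch(analysis,
    quadratic          = fit_quadratic_ols(y, x),
    quadratic_centered = fit_quadratic_ols(y, x),
    interaction        = fit_interaction_ols(y, x, data$z[idx]),
    logistic           = fit_logistic_quadratic(y, x))
}

# Target coefficient, its variance, and a confidence interval (t with
# residual df for OLS, Wald normal for logistic).
target_summary <- function(fit, conf_level = 0.95) {
  i <- fit$term_index
  est <- fit$coefficients[[i]]
  v <- fit$covariance[i, i]
  crit <- if (fit$kind == "ols") qt(1 - (1 - conf_level) / 2, fit$residual_df)
          else qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(v)
  list(estimate = est, variance = v, se = se,
       ci_low = est - crit * se, ci_high = est + crit * se)
}
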