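# Data generation for the simulation designs: covariates with mean 2 and
# variance 1, linear or logistic outcomes, and expit-based missingness in X
# calibrated to a target marginal observation probability.

# log X ~ N(log(3.2)/2, log(5/4)) is the unique log-normal with mean 2 and
# variance 1; its skewness is (exp(s^2)+2)*sqrt(exp(s^2)-1) = 1.625.
.LN_MU <- log(3.2) / 2
.LN_S2 <- log(5 / 4)

#' Covariate distribution specification
#'
#' All four families have marginal mean 2 and variance 1.  The log-normal has
#' skewness 1.63 and the shifted/scaled beta (`12.05*(B - 1/11) + 2` with
#' `B ~ Beta(1, 10)`) skewness 1.51; the uniform is `U(2 - sqrt(3),
#' 2 + sqrt(3))`.  For bivariate designs `correlation` is imposed on the
#' natural scale (normal family) or the log scale (log-normal family).
#'
#' @param family one of `"normal"`, `"lognormal"`, `"beta_shifted"`,
#'   `"uniform"`.
#' @param correlation correlation between the two covariates of a bivariate
#'   design, strictly inside (-1, 1).  Ignored for univariate draws.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(family = c("normal", "lognormal", "beta_shifted",
                                      "uniform"),
                           correlation = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(correlation), length(correlation) == 1L,
            is.finite(correlation))
  if (abs(correlation) >= 1)
    stop("correlation must lie strictly within (-1, 1)")
  structure(list(family = family, correlation = correlation),
            class = "covariate_spec")
}

#' Draw covariates
#'
#' Draws `n` i.i.d. covariate values from the family in `spec`, or, with
#' `bivariate = TRUE`, `n` pairs (X, Z) with the specified correlation.
#' Uses the current RNG stream; seed with [set.seed()].
#'
#' @param spec a [covariate_spec()].
#' @param n number of draws (>= 1).
#' @param bivariate draw correlated pairs (normal and log-normal families
#'   only)?
#' @return a numeric vector, or an `n x 2` matrix with columns `x`, `z`.
#' @export
make_covariates <- function(spec, n, bivariate = FALSE) {
  stopifnot(inherits(spec, "covariate_spec"), n >= 1)
  if (!bivariate) {
    return(switch(spec$family,
      normal       = rnorm(n, 2, 1),
      lognormal    = exp(rnorm(n, .LN_MU, sqrt(.LN_S2))),
      beta_shifted = 12.05 * (rbeta(n, 1, 10) - 1 / 11) + 2,
      uniform      = runif(n, 2 - sqrt(3), 2 + sqrt(3))))
  }
  rho <- spec$correlation
  e1 <- rnorm(n)
  e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)
  out <- switch(spec$family,
    normal    = cbind(2 + e1, 2 + e2),
    lognormal = cbind(exp(.LN_MU + sqrt(.LN_S2) * e1),
                      exp(.LN_MU + sqrt(.LN_S2) * e2)),
    stop("bivariate draws are defined for the normal and lognormal families"))
  colnames(out) <- c("x", "z")
  out
}

# Conditional mean of the linear outcome models.
outcome_mean <- function(kind, x, z = NULL) {
  switch(kind,
    linear_quadratic          = 2 * x + x^2,
    linear_quadratic_centered = (x - 2)^2,
    linear_interaction        = {
      if (is.null(z)) stop("interaction outcome requires z")
      x + z + x * z
    },
    stop("unknown linear outcome kind: ", kind))
}

# Var(m(X)) for the linear designs: closed form under the normal family
# (Var(2X + X^2) = 38, Var((X-2)^2) = 2 at mu = 2, sigma^2 = 1), otherwise a
# fixed-seed Monte-Carlo moment estimate.
outcome_mean_variance <- function(kind, spec, n_mc = 1e6,
                                  calib_seed = 60901L) {
  if (spec$family == "normal" && spec$correlation == 0) {
    if (kind == "linear_quadratic") return(38)
    if (kind == "linear_quadratic_centered") return(2)
  }
  local_seed(calib_seed, {
    if (kind == "linear_interaction") {
      xz <- make_covariates(spec, n_mc, bivariate = TRUE)
      var(outcome_mean(kind, xz[, 1], xz[, 2]))
    } else {
      var(outcome_mean(kind, make_covariates(spec, n_mc)))
    }
  })
}

#' Residual variance reaching a target R-squared
#'
#' For the linear outcome models `Y = m(X[, Z]) + e`, returns the residual
#' variance `phi = Var(m) * (1 - r_squared) / r_squared` so that the
#' coefficient of determination of the true regression equals `r_squared`.
#' `Var(m)` uses closed-form normal moments where available and otherwise a
#' fixed-seed Monte-Carlo estimate, making `phi` a scenario constant.
#'
#' @param kind `"linear_quadratic"`, `"linear_quadratic_centered"` or
#'   `"linear_interaction"`.
#' @param spec a [covariate_spec()].
#' @param r_squared target R-squared, strictly inside (0, 1).
#' @param n_mc Monte-Carlo sample size for non-closed-form families.
#' @param calib_seed fixed seed for the Monte-Carlo moment sample.
#' @return the residual variance `phi`.
#' @export
calibrate_noise_variance <- function(kind, spec, r_squared, n_mc = 1e6,
                                     calib_seed = 60901L) {
  stopifnot(is.numeric(r_squared), length(r_squared) == 1L)
  if (r_squared <= 0 || r_squared >= 1)
    stop("r_squared must lie strictly within (0, 1)")
  v <- outcome_mean_variance(kind, spec, n_mc, calib_seed)
  v * (1 - r_squared) / r_squared
}

#' Generate a linear outcome
#'
#' `y_i = m(x_i[, z_i]) + e_i` with `e_i ~ N(0, phi)` i.i.d., where `m` is
#' `2X + X^2`, `(X - 2)^2` or `X + Z + XZ` according to `kind`.
#'
#' @param x covariate vector.
#' @param kind linear outcome kind (see [calibrate_noise_variance()]).
#' @param phi residual variance (>= 0).
#' @param z second covariate, required for the interaction kind.
#' @return numeric outcome vector.
#' @export
make_linear_outcome <- function(x, kind, phi, z = NULL) {
  stopifnot(phi >= 0)
  if (!is.null(z) && length(z) != length(x)) stop("x and z lengths differ")
  m <- outcome_mean(kind, x, z)
  m + rnorm(length(x), 0, sqrt(phi))
}

#' Logistic intercept reaching a target marginal outcome probability
#'
#' Solves `E[expit(beta0 + 2*beta2*X + beta2*X^2)] = marginal_p` over the
#' covariate distribution for `beta0`, using a fixed-seed Monte-Carlo sample
#' so the intercept is a scenario constant.  With this parameterisation the
#' log odds ratio comparing X = 3 to X = 1 equals `12 * beta2`.
#'
#' @param beta2 quadratic coefficient.
#' @param spec a [covariate_spec()].
#' @param marginal_p target marginal `P(Y = 1)`, strictly inside (0, 1).
#' @param n_mc,calib_seed Monte-Carlo sample size and fixed seed.
#' @return the intercept `beta0`.
#' @export
calibrate_logistic_intercept <- function(beta2, spec, marginal_p,
                                         n_mc = 1e6, calib_seed = 60901L) {
  if (marginal_p <= 0 || marginal_p >= 1)
    stop("marginal_p must lie strictly within (0, 1)")
  x <- local_seed(calib_seed, make_covariates(spec, n_mc))
  lin <- 2 * beta2 * x + beta2 * x^2
  f <- function(b0) mean(plogis(b0 + lin)) - marginal_p
  uniroot(f, c(-50, 50), extendInt = "upX", tol = 1e-10)$root
}

#' Generate a binary outcome from the quadratic logistic model
#'
#' `y_i ~ Bernoulli(expit(beta0 + 2*beta2*x_i + beta2*x_i^2))`.
#'
#' @param x covariate vector.
#' @param beta0 intercept (see [calibrate_logistic_intercept()]).
#' @param beta2 quadratic coefficient.
#' @return integer 0/1 vector.
#' @export
make_binary_outcome <- function(x, beta0, beta2) {
  rbinom(length(x), 1L, plogis(beta0 + 2 * beta2 * x + beta2 * x^2))
}

#' Missingness intercept reaching a target observation probability
#'
#' The observation indicator is `R ~ Bernoulli(expit(alpha0 + alpha1 * Y))`.
#' Given `alpha1` and a population-scale reference sample of Y, solves for
#' the `alpha0` at which the marginal observation probability equals
#' `target_obs`.  With `alpha1 = 0` (MCAR) this is `logit(target_obs)` in
#' closed form; `target_obs = 1` returns `Inf` (no missingness).
#'
#' @param alpha1 coefficient of Y in the mechanism.
#' @param y_reference numeric sample from the scenario's Y distribution.
#' @param target_obs target marginal observation probability in (0, 1].
#' @return the intercept `alpha0`.
#' @export
calibrate_missingness_intercept <- function(alpha1, y_reference,
                                            target_obs = 0.7) {
  if (target_obs <= 0 || target_obs > 1)
    stop("target_obs must lie within (0, 1]")
  if (target_obs == 1) return(Inf)
  if (alpha1 == 0) return(qlogis(target_obs))
  f <- function(a0) mean(plogis(a0 + alpha1 * y_reference)) - target_obs
  uniroot(f, c(-50, 50), extendInt = "upX", tol = 1e-10)$root
}

#' Apply the missingness mechanism
#'
#' Draws the observation indicator `r_i ~ Bernoulli(expit(alpha0 +
#' alpha1 * y_i))` independently; `alpha1 = 0` gives MCAR.
#'
#' @param y outcome vector (the mechanism depends on Y only, so X is MAR).
#' @param alpha0,alpha1 mechanism parameters.
#' @return integer 0/1 vector, 1 = X observed.
#' @export
apply_missingness <- function(y, alpha0, alpha1) {
  rbinom(length(y), 1L, plogis(alpha0 + alpha1 * y))
}

#' One replicate's incomplete data
#'
#' Container for an outcome `y`, an incomplete covariate `x` (NA where
#' unobserved), an optional fully observed covariate `z`, and the
#' observation indicator `r` (`r[i] == 1` iff `x[i]` is observed).  In
#' simulations the pre-deletion covariate can be kept in `x_true` for the
#' complete-data reference analysis.
#'
#' @param y numeric (or 0/1) outcome vector, fully observed.
#' @param x covariate vector with NA entries where unobserved.
#' @param r observation indicator; defaults to `!is.na(x)`.
#' @param z optional fully observed covariate.
#' @param x_true optional pre-deletion covariate values.
#' @return an object of class `incomplete_dataset`.
#' @export
incomplete_dataset <- function(y, x, r = as.integer(!is.na(x)), z = NULL,
                               x_true = NULL) {
  n <- length(y)
  stopifnot(length(x) == n, length(r) == n, all(r %in% c(0L, 1L)))
  if (anyNA(y)) stop("y must be fully observed")
  if (any(is.na(x) & r == 1L)) stop("x must be present wherever r = 1")
  if (any(!is.na(x) & r == 0L)) x[r == 0L] <- NA_real_
  if (!is.null(z)) {
    stopifnot(length(z) == n)
    if (anyNA(z)) stop("z must be fully observed")
  }
  if (!is.null(x_true)) stopifnot(length(x_true) == n, !anyNA(x_true))
  structure(list(y = as.numeric(y), x = as.numeric(x), z = z,
                 r = as.integer(r), x_true = x_true, n = n,
                 n1 = sum(r == 1L)),
            class = "incomplete_dataset")
}

#' @export
print.incomplete_dataset <- function(x, ...) {
  cat("Incomplete dataset: n =", x$n, ", complete cases n1 =", x$n1,
      if (!is.null(x$z)) ", with z" else "", "\n")
  invisible(x)
}
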