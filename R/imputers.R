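# The three imputation strategies.  Passive and PMM share a Bayesian
# univariate linear imputation model for X given W = (1, Y[, Z[, YZ]]):
# fit on complete cases, draw (sigma*, gamma*) from the standard
# noninformative posterior, then either generate X directly (passive) or
# borrow an observed X from the K nearest complete cases on the fitted value
# (PMM).  JAV fits the bivariate regression of (X, derived) on W and imputes
# the pair jointly, ignoring the functional link between X and the derived
# term.

#' Fit the univariate linear imputation model on complete cases
#'
#' Least-squares fit of X on the predictor set among the `n1` complete
#' cases, with the unbiased residual variance (divisor `n1 - q`) and
#' `psi = (W'W)^{-1}` needed for posterior draws.
#'
#' @param data an [incomplete_dataset()].
#' @param predictors character subset of `c("y", "z", "yz")`; an intercept
#'   is always included, so `q = length(predictors) + 1`.
#' @return an object of class `cc_linear_fit` with elements `gamma_hat`,
#'   `sigma2_hat`, `psi`, `n1`, `q` and the full-sample design matrix used
#'   for prediction on incomplete rows.
#' @export
fit_cc_linear <- function(data, predictors = "y") {
  stopifnot(inherits(data, "incomplete_dataset"))
  W_all <- design_matrix(data, predictors)
  cc <- data$r == 1L
  n1 <- sum(cc)
  q <- ncol(W_all)
  if (n1 <= q) stop("too few complete cases: n1 <= q")
  W <- W_all[cc, , drop = FALSE]
  psi <- tryCatch(chol2inv(chol(crossprod(W))),
                  error = function(e)
                    stop("singular complete-case design", call. = FALSE))
  gamma_hat <- drop(psi %*% crossprod(W, data$x[cc]))
  rss <- sum((data$x[cc] - drop(W %*% gamma_hat))^2)
  structure(list(gamma_hat = gamma_hat, sigma2_hat = rss / (n1 - q),
                 psi = psi, n1 = n1, q = q, predictors = predictors,
                 W_all = W_all),
            class = "cc_linear_fit")
}

#' Draw imputation-model parameters from their posterior
#'
#' Under the noninformative prior proportional to `1/sigma^2`,
#' `sigma*^2 = (n1 - q) * sigma2_hat / chisq(n1 - q)` and
#' `gamma* ~ N(gamma_hat, psi * sigma*^2)`.
#'
#' @param fit a [fit_cc_linear()] result.
#' @return an object of class `posterior_draw` with `gamma_star` and
#'   `sigma_star`.
#' @export
draw_linear_posterior <- function(fit) {
  stopifnot(inherits(fit, "cc_linear_fit"))
  df <- fit$n1 - fit$q
  sigma_star2 <- if (fit$sigma2_hat == 0) 0 else
    df * fit$sigma2_hat / rchisq(1L, df)
  gamma_star <- fit$gamma_hat +
    sqrt(sigma_star2) * drop(t(chol(fit$psi)) %*% rnorm(fit$q))
  structure(list(gamma_star = gamma_star, sigma_star = sqrt(sigma_star2)),
            class = "posterior_draw")
}

# Completed-data container: x fully filled, plus the derived term (X^2 or
# XZ).  For passive and PMM the derived term equals the transform of x by
# construction; for JAV it is imputed separately and need not.
completed_dataset <- function(data, x, derived) {
  structure(list(y = data$y, x = x, z = data$z, derived = derived,
                 r = data$r, n = data$n),
            class = "completed_dataset")
}

derived_term <- function(x, z, analysis) {
  if (analysis == "quadratic") x^2 else x * z
}

#' Passive imputation ("impute then transform")
#'
#' Replaces each missing `x_i` by `gamma*' W_i + sigma* B_i` with
#' `B_i ~ N(0, 1)`, then computes the derived term (X^2 or XZ) from the
#' imputed value, so `derived == x^2` (or `x * z`) holds on every row.
#'
#' @param data an [incomplete_dataset()].
#' @param draw a [draw_linear_posterior()] result.
#' @param fit the [fit_cc_linear()] the draw came from.
#' @param analysis `"quadratic"` (derived term X^2) or `"interaction"` (XZ).
#' @return a `completed_dataset`.
#' @export
impute_passive <- function(data, draw, fit,
                           analysis = c("quadratic", "interaction")) {
  analysis <- match.arg(analysis)
  x <- data$x
  miss <- which(data$r == 0L)
  if (length(miss)) {
    mu <- drop(fit$W_all[miss, , drop = FALSE] %*% draw$gamma_star)
    x[miss] <- mu + draw$sigma_star * rnorm(length(miss))
  }
  completed_dataset(data, x, derived_term(x, data$z, analysis))
}

#' Predictive mean matching
#'
#' Computes the fitted value `Xhat*_i = gamma*' W_i` for every subject; for
#' each incomplete case the donor pool is the `K` complete cases with the
#' nearest fitted values, one of which is chosen uniformly at random and its
#' observed X becomes the imputed value.  Ties in distance are broken by a
#' random permutation of the complete cases; with fewer than `K` complete
#' cases the pool is all of them.  The derived term is computed from the
#' imputed X.
#'
#' @inheritParams impute_passive
#' @param K donor pool size (>= 1); 5 is the conventional default.
#' @return a `completed_dataset`; every imputed X occurs among the observed
#'   X values.
#' @export
impute_pmm <- function(data, draw, fit, K = 5L,
                       analysis = c("quadratic", "interaction")) {
  analysis <- match.arg(analysis)
  stopifnot(K >= 1)
  obs <- which(data$r == 1L)
  if (!length(obs)) stop("PMM requires at least one complete case")
  x <- data$x
  miss <- which(data$r == 0L)
  if (length(miss)) {
    xb <- drop(fit$W_all %*% draw$gamma_star)
    perm <- obs[sample.int(length(obs))]
    xb_obs <- xb[perm]
    Keff <- min(K, length(obs))
    for (i in miss) {
      nearest <- order(abs(xb_obs - xb[i]))[seq_len(Keff)]
      donor <- perm[nearest[sample.int(Keff, 1L)]]
      x[i] <- data$x[donor]
    }
  }
  completed_dataset(data, x, derived_term(x, data$z, analysis))
}

#' Fit the bivariate (JAV) imputation model on complete cases
#'
#' Multivariate least squares of the response pair (X, derived term) on the
#' predictor set, among complete cases.  Returns the coefficient matrix
#' `delta_hat` (q x 2), the residual sum-of-cross-products matrix `S`, the
#' ML-scale residual covariance `tau_hat = S / n1`, and `psi = (W'W)^{-1}`.
#'
#' @inheritParams impute_passive
#' @param predictors character subset of `c("y", "z", "yz")`.
#' @return an object of class `cc_mvreg_fit`.
#' @export
fit_cc_mvreg <- function(data, predictors = "y",
                         analysis = c("quadratic", "interaction")) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(data, "incomplete_dataset"))
  W_all <- design_matrix(data, predictors)
  cc <- data$r == 1L
  n1 <- sum(cc)
  q <- ncol(W_all)
  if (n1 <= q + 1L) stop("too few complete cases: n1 <= q + 1")
  W <- W_all[cc, , drop = FALSE]
  V <- cbind(data$x, derived_term(data$x, data$z, analysis))[cc, , drop = FALSE]
  psi <- tryCatch(chol2inv(chol(crossprod(W))),
                  error = function(e)
                    stop("singular complete-case design", call. = FALSE))
  delta_hat <- psi %*% crossprod(W, V)
  resid <- V - W %*% delta_hat
  S <- crossprod(resid)
  structure(list(delta_hat = delta_hat, S = S, tau_hat = S / n1, psi = psi,
                 n1 = n1, q = q, predictors = predictors, W_all = W_all,
                 analysis = analysis),
            class = "cc_mvreg_fit")
}

#' Draw bivariate imputation-model parameters from their posterior
#'
#' The standard noninformative multivariate-regression posterior, the direct
#' generalisation of the univariate recipe: the residual covariance
#' `tau*` is inverse-Wishart with `n1 - q` degrees of freedom and scale the
#' residual sum-of-cross-products matrix, and `delta*` is matrix-normal with
#' mean `delta_hat`, row covariance `psi` and column covariance `tau*`.
#' Near-singular scale matrices are ridged by `ridge` on the diagonal with a
#' warning.
#'
#' @param fit a [fit_cc_mvreg()] result.
#' @param ridge diagonal ridge applied when the residual cross-product
#'   matrix is numerically singular.
#' @return an object of class `mv_posterior_draw` with `delta_star` (q x 2)
#'   and `tau_star` (2 x 2, symmetric positive-definite).
#' @export
draw_mv_posterior <- function(fit, ridge = 1e-10) {
  stopifnot(inherits(fit, "cc_mvreg_fit"))
  df <- fit$n1 - fit$q
  if (df < 2) stop("n1 - q < 2: Wishart draw undefined")
  S <- fit$S
  if (!all(is.finite(S)) || rcond(S) < 1e-12) {
    warning("near-singular residual cross-product matrix; ridging diagonal")
    S <- S + diag(ridge, 2L)
  }
  tau_star <- chol2inv(chol(rWishart(1L, df, chol2inv(chol(S)))[, , 1]))
  tau_star <- (tau_star + t(tau_star)) / 2
  L <- t(chol(fit$psi))
  C <- t(chol(tau_star))
  Z <- matrix(rnorm(2L * fit$q), fit$q, 2L)
  delta_star <- fit$delta_hat + L %*% Z %*% t(C)
  structure(list(delta_star = delta_star, tau_star = tau_star),
            class = "mv_posterior_draw")
}

#' Just-another-variable (JAV) imputation
#'
#' For each incomplete case the pair (X, derived term) is drawn jointly from
#' the bivariate normal with mean `delta*' W_i` and covariance `tau*`.  The
#' derived term is *not* recomputed from the imputed X, so imputed pairs
#' need not satisfy `derived == x^2`; observed rows keep their exact
#' transform.
#'
#' @param data an [incomplete_dataset()].
#' @param draw a [draw_mv_posterior()] result.
#' @param fit the [fit_cc_mvreg()] the draw came from.
#' @return a `completed_dataset`.
#' @export
impute_jav <- function(data, draw, fit) {
  x <- data$x
  derived <- derived_term(data$x, data$z, fit$analysis)
  miss <- which(data$r == 0L)
  if (length(miss)) {
    mu <- fit$W_all[miss, , drop = FALSE] %*% draw$delta_star
    if (max(abs(draw$tau_star)) > 0) {
      noise <- matrix(rnorm(2L * length(miss)), length(miss), 2L) %*%
        chol(draw$tau_star)
    } else {
      noise <- 0
    }
    imp <- mu + noise
    x[miss] <- imp[, 1]
    derived[miss] <- imp[, 2]
  }
  completed_dataset(data, x, derived)
}

# Default imputation predictor sets: the quadratic designs impute from Y
# alone; for the interaction designs passive uses (Y, Z), PMM additionally
# includes YZ, and JAV conditions the pair (X, XZ) on (Y, Z).
default_predictors <- function(analysis, method) {
  if (analysis == "quadratic") return("y")
  switch(method,
         passive = c("y", "z"),
         pmm     = c("y", "z", "yz"),
         jav     = c("y", "z"))
}

#' Create M multiply imputed datasets
#'
#' Fits the relevant imputation model once on the complete cases, then draws
#' parameters and imputes M times independently.
#'
#' @param data an [incomplete_dataset()].
#' @param method `"passive"`, `"pmm"` or `"jav"`.
#' @param M number of imputations (>= 2).
#' @param K PMM donor pool size.
#' @param analysis `"quadratic"` or `"interaction"`; sets the derived term.
#' @param predictors optional predictor set overriding the method default
#'   (e.g. `c("y", "z", "yz")` to add the YZ term to a passive imputation
#'   model for an interaction analysis).
#' @return a list of M `completed_dataset` objects.
#' @export
multiply_impute <- function(data, method = c("passive", "pmm", "jav"),
                            M = 5L, K = 5L,
                            analysis = c("quadratic", "interaction"),
                            predictors = NULL) {
  method <- match.arg(method)
  analysis <- match.arg(analysis)
  if (M < 2) stop("M must be at least 2")
  if (is.null(predictors)) predictors <- default_predictors(analysis, method)
  if (method == "jav") {
    fit <- fit_cc_mvreg(data, predictors, analysis)
    lapply(seq_len(M), function(m) impute_jav(data, draw_mv_posterior(fit), fit))
  } else {
    fit <- fit_cc_linear(data, predictors)
    lapply(seq_len(M), function(m) {
      draw <- draw_linear_posterior(fit)
      if (method == "passive") impute_passive(data, draw, fit, analysis)
      else impute_pmm(data, draw, fit, K, analysis)
    })
  }
}
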