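# Passive, PMM and JAV imputation: fits, posterior draws, and the
# functional-consistency properties that distinguish the three strategies.

test_that("the complete-case linear fit matches the normal-equation oracle", {
  d <- toy_data(n = 80, seed = 1)
  fit <- fit_cc_linear(d, "y")
  cc <- d$r == 1L
  W <- cbind(1, d$y[cc])
  expect_equal(unname(fit$gamma_hat), ols_oracle(d$x[cc], W), tolerance = 1e-8)
  res <- d$x[cc] - drop(W %*% fit$gamma_hat)
  expect_equal(fit$sigma2_hat, sum(res^2) / (fit$n1 - 2), tolerance = 1e-10)
  expect_true(isSymmetric(fit$psi))
  expect_true(all(eigen(fit$psi, only.values = TRUE)$values > 0))
})

test_that("a noiseless X|Y relation gives sigma2_hat = 0 and recovers the line", {
  d <- noiseless_data()
  fit <- fit_cc_linear(d, "y")
  expect_equal(fit$sigma2_hat, 0, tolerance = 1e-20)
  expect_equal(unname(fit$gamma_hat), c(0.5, 0.25), tolerance = 1e-10)
  # degenerate posterior: draw collapses to the MLE
  draw <- draw_linear_posterior(fit)
  expect_equal(draw$sigma_star, 0)
  expect_equal(draw$gamma_star, fit$gamma_hat)
  # and passive imputation returns the fitted values exactly
  comp <- impute_passive(d, draw, fit)
  expect_equal(comp$x, 0.5 + 0.25 * d$y, tolerance = 1e-10)
})

test_that("interaction predictor sets give q = 3 (Passive1) and q = 4 (Passive2)", {
  d <- toy_data(n = 80, with_z = TRUE, seed = 2)
  expect_equal(fit_cc_linear(d, c("y", "z"))$q, 3L)
  expect_equal(fit_cc_linear(d, c("y", "z", "yz"))$q, 4L)
  expect_error(fit_cc_linear(toy_data(n = 80, seed = 2), c("y", "z")), "z")
})

test_that("posterior draws follow the scaled inverse-chi-squared / normal law", {
  d <- toy_data(n = 22, p_miss = 0.1, seed = 3)  # small n1 so the df matter
  fit <- fit_cc_linear(d, "y")
  df <- fit$n1 - fit$q
  set.seed(301)
  draws <- replicate(2e4, {
    dr <- draw_linear_posterior(fit)
    c(dr$sigma_star^2, (dr$gamma_star - fit$gamma_hat) / dr$sigma_star)
  })
  # E[sigma*^2] = df * sigma2_hat / (df - 2)
  expect_lt(abs(mean(draws[1, ]) - df * fit$sigma2_hat / (df - 2)),
            3 * sd(draws[1, ]) / sqrt(ncol(draws)))
  # (gamma* - gamma_hat)/sigma* ~ N(0, psi)
  emp <- cov(t(draws[2:3, ]))
  expect_lt(max(abs(emp - fit$psi)), 0.05 * max(abs(fit$psi)))
})

test_that("passive imputation preserves observed rows and the functional link", {
  d <- toy_data(n = 100, seed = 4)
  fit <- fit_cc_linear(d, "y")
  set.seed(401)
  comp <- impute_passive(d, draw_linear_posterior(fit), fit)
  obs <- d$r == 1L
  expect_identical(comp$x[obs], d$x[obs])
  expect_false(anyNA(comp$x))
  expect_equal(comp$derived, comp$x^2)     # derived = x^2 exactly, all rows
  # fully observed input is a no-op
  full <- incomplete_dataset(y = d$y, x = d$x_true, r = rep(1L, d$n))
  ffit <- fit_cc_linear(full, "y")
  fcomp <- impute_passive(full, draw_linear_posterior(ffit), ffit)
  expect_identical(fcomp$x, full$x)
})

test_that("PMM imputes only realised values, from the nearest donors", {
  d <- toy_data(n = 100, seed = 5)
  fit <- fit_cc_linear(d, "y")
  set.seed(501)
  draw <- draw_linear_posterior(fit)
  comp <- impute_pmm(d, draw, fit, K = 5)
  miss <- d$r == 0L
  expect_true(all(comp$x[miss] %in% d$x[d$r == 1L]))
  expect_equal(comp$derived, comp$x^2)
  # with the single-predictor model {1, Y}, matching on fitted values is
  # matching on Y: each donor must be among the K nearest observed Y values
  obs_idx <- which(d$r == 1L)
  for (i in which(miss)) {
    donor <- obs_idx[which(d$x[obs_idx] == comp$x[i])][1]
    ranks <- rank(abs(d$y[obs_idx] - d$y[i]), ties.method = "min")
    expect_lte(ranks[obs_idx == donor], 5)
  }
})

test_that("PMM with binary Y draws donors with the same outcome", {
  set.seed(502)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  x <- rnorm(n, 2 + y, 1)
  r <- rbinom(n, 1L, 0.7)
  d <- incomplete_dataset(y = y, x = ifelse(r == 1, x, NA), r = r)
  fit <- fit_cc_linear(d, "y")
  draw <- draw_linear_posterior(fit)
  comp <- impute_pmm(d, draw, fit, K = 5)
  for (i in which(d$r == 0L)) {
    donors <- which(d$r == 1L & d$x == comp$x[i])
    expect_true(all(y[donors] == y[i]))
  }
})

test_that("the bivariate (JAV) fit equals two univariate least-squares fits", {
  d <- toy_data(n = 80, seed = 6)
  fit <- fit_cc_mvreg(d, "y", "quadratic")
  cc <- d$r == 1L
  W <- cbind(1, d$y[cc])
  expect_equal(unname(fit$delta_hat[, 1]), ols_oracle(d$x[cc], W),
               tolerance = 1e-8)
  expect_equal(unname(fit$delta_hat[, 2]), ols_oracle(d$x[cc]^2, W),
               tolerance = 1e-8)
  expect_equal(fit$q, 2L)
  # responses exactly linear in the predictors give a zero residual
  # covariance (constant X, so X and X^2 are both fitted without error)
  nd <- incomplete_dataset(y = 1:20, x = c(rep(3, 15), rep(NA, 5)),
                           r = rep(c(1L, 0L), c(15L, 5L)))
  nfit <- fit_cc_mvreg(nd, "y", "quadratic")
  expect_lt(max(abs(nfit$tau_hat)), 1e-10)
})

test_that("multivariate posterior draws are SPD with the stated moments", {
  d <- toy_data(n = 60, p_miss = 0.2, seed = 7)
  fit <- fit_cc_mvreg(d, "y", "quadratic")
  df <- fit$n1 - fit$q
  set.seed(701)
  taus <- matrix(0, 3, 2e4)
  std <- matrix(0, 2, 2e4)
  for (j in seq_len(ncol(taus))) {
    dr <- draw_mv_posterior(fit)
    ev <- eigen(dr$tau_star, only.values = TRUE)$values
    expect_true(all(ev > 0))
    taus[, j] <- dr$tau_star[c(1, 2, 4)]
    # column-1 coefficients, standardised by their own tau11: ~ N(0, psi)
    std[, j] <- (dr$delta_star[, 1] - fit$delta_hat[, 1]) /
      sqrt(dr$tau_star[1, 1])
  }
  # inverse-Wishart mean: S / (df - p - 1) with p = 2
  expect_equal(rowMeans(taus), fit$S[c(1, 2, 4)] / (df - 3),
               tolerance = 0.05)
  # marginal law of one response's coefficients matches the univariate recipe
  expect_lt(max(abs(cov(t(std)) - fit$psi)), 0.06 * max(abs(fit$psi)))
})

test_that("JAV imputes the pair jointly, breaking the functional link", {
  d <- toy_data(n = 200, p_miss = 0.4, seed = 8)
  fit <- fit_cc_mvreg(d, "y", "quadratic")
  set.seed(801)
  comp <- impute_jav(d, draw_mv_posterior(fit), fit)
  obs <- d$r == 1L
  expect_identical(comp$x[obs], d$x[obs])
  expect_equal(comp$derived[obs], d$x[obs]^2)
  # imputed derived values are not the square of imputed x
  miss <- !obs
  expect_gt(max(abs(comp$derived[miss] - comp$x[miss]^2)), 1e-6)
  # a zero-covariance draw returns the bivariate fitted means
  draw0 <- structure(list(delta_star = fit$delta_hat,
                          tau_star = matrix(0, 2, 2)),
                     class = "mv_posterior_draw")
  comp0 <- impute_jav(d, draw0, fit)
  mu <- fit$W_all[miss, ] %*% fit$delta_hat
  expect_equal(comp0$x[miss], unname(mu[, 1]))
  expect_equal(comp0$derived[miss], unname(mu[, 2]))
})

test_that("JAV-completed moments under MCAR estimate the population moments", {
  # population values for X ~ N(2,1), Y = 2X + X^2 + e at R^2 = 0.5:
  # E X = 2, E X^2 = 5, E Y = 9
  cfg <- scenario_config("quadratic", "normal", mechanism = "MCAR",
                         r_squared = 0.5, n = 20000, reps = 1, methods = "jav",
                         seed = 802)
  calib <- calibrate_scenario(cfg)
  set.seed(803)
  d <- generate_replicate(cfg, calib)
  fit <- fit_cc_mvreg(d, "y", "quadratic")
  comp <- impute_jav(d, draw_mv_posterior(fit), fit)
  tol <- 3 * c(sqrt(1), sqrt(18), sqrt(76)) / sqrt(20000)
  expect_lt(abs(mean(comp$x) - 2), tol[1] * 1.5)       # imputation noise adds
  expect_lt(abs(mean(comp$derived) - 5), tol[2] * 1.5)
  expect_lt(abs(mean(comp$y) - 9), tol[3])
  expect_lt(abs(var(comp$x) - 1) / 1, 0.05)
  expect_lt(abs(var(comp$derived) - 18) / 18, 0.08)
})

test_that("multiply_impute is deterministic given the seed and validates M", {
  d <- toy_data(n = 100, seed = 9)
  expect_error(multiply_impute(d, "passive", M = 1), "M")
  set.seed(901)
  a <- multiply_impute(d, "jav", M = 5)
  set.seed(901)
  b <- multiply_impute(d, "jav", M = 5)
  expect_identical(a, b)
  expect_length(a, 5L)
  # fully observed input: all M outputs identical to the input
  full <- incomplete_dataset(y = d$y, x = d$x_true, r = rep(1L, d$n))
  set.seed(902)
  imps <- multiply_impute(full, "pmm", M = 3)
  for (m in 1:3) expect_identical(imps[[m]]$x, full$x)
})
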