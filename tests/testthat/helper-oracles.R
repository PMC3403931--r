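# Independent oracles and small fixture builders used across the suite.

# sample skewness (population-style divisor; bias negligible at the sizes used)
skewness <- function(x) mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5

# brute-force least squares straight from the normal equations
ols_oracle <- function(y, U) unname(drop(solve(t(U) %*% U, t(U) %*% y)))

# logistic log-likelihood score at beta, for the self-check oracle
logistic_score <- function(beta, y, U) {
  drop(t(U) %*% (y - plogis(drop(U %*% beta))))
}

# a small incomplete dataset with a known linear X|Y structure
toy_data <- function(n = 60, p_miss = 0.3, with_z = FALSE, noise = 1,
                     seed = 42) {
  set.seed(seed)
  x <- rnorm(n, 2, 1)
  z <- if (with_z) rnorm(n, 2, 1) else NULL
  y <- if (with_z) x + z + x * z + rnorm(n, 0, 2) else 2 * x + x^2 + rnorm(n, 0, 2)
  r <- rbinom(n, 1L, 1 - p_miss)
  # noisy x given y so the imputation model has residual variance
  incomplete_dataset(y = y, x = ifelse(r == 1, x, NA), r = r, z = z,
                     x_true = x)
}

# incomplete data where X is exactly linear in Y on the complete cases
noiseless_data <- function(n = 30) {
  y <- seq_len(n)
  x <- 0.5 + 0.25 * y
  r <- rep_len(c(1L, 1L, 0L), n)
  incomplete_dataset(y = y, x = ifelse(r == 1, x, NA), r = r, x_true = x)
}
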