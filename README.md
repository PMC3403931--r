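# minonlin

Multiple imputation of a missing covariate **X** when the analysis model
contains more than one function of it — a quadratic term `Y ~ X + X²` or an
interaction `Y ~ X + Z + XZ`.  Written for biostatisticians and
methodologists who need to impute such covariates, or to evaluate how the
standard strategies behave under MCAR and MAR missingness.

Because the imputed `X` and the imputed `X²` must somehow relate, MI
software offers three distinct strategies, all implemented here:

* **Passive imputation** ("impute then transform"): fit the Bayesian linear
  regression `X ~ N(γ'W, σ²)` on the `n1` complete cases (`W = (1, Y)` or
  `(1, Y, Z[, YZ])`), draw `σ*² = (n1−q)σ̂²/χ²(n1−q)` and
  `γ* ~ N(γ̂, ψσ*²)` with `ψ = (W'W)⁻¹`, impute `X_i = γ*'W_i + σ*B_i`,
  then *compute* `X²` (or `XZ`) from the imputed value.
* **Predictive mean matching (PMM)**: same fit and draw, but each
  incomplete case borrows the observed `X` of one of the `K = 5` complete
  cases with the nearest perturbed fitted value `X̂* = γ*'W`.
* **JAV** ("just another variable" / "transform then impute"): treat the
  pair `(X, X²)` as unrelated variables, assume `(Y, X, X²)` is jointly
  normal, and impute the pair from its conditional bivariate normal given
  `Y` with inverse-Wishart / matrix-normal perturbed parameters.  Imputed
  pairs deliberately need not satisfy `X² = (X)²`.

Per-imputation analysis fits (OLS or logistic ML) are pooled by **Rubin's
Rules**: estimate = mean, total variance `W̄ + (1 + 1/M)B`, df
`(M−1)(1 + W̄/((1+1/M)B))²`.

JAV is consistent for linear analysis models when X is MCAR but generally
biased under MAR, and can fail dramatically for logistic models; passive
imputation attenuates the quadratic/interaction effect; PMM sits in
between.  The package's simulation harness reproduces this entire
evaluation: covariates with mean 2 and variance 1 (normal, log-normal,
shifted beta, uniform), linear and logistic outcome models calibrated to a
target R² or marginal outcome probability, and expit missingness in X
calibrated to 70% observation.

## Worked example

```r
library(minonlin)
set.seed(2024)
x <- rnorm(300, mean = 2, sd = 1)
y <- 2 * x + x^2 + rnorm(300, sd = sqrt(38))   # R^2 = 0.5
r <- apply_missingness(y, alpha0 = logit(0.7), alpha1 = 0)  # 30% MCAR
d <- incomplete_dataset(y = y, x = ifelse(r == 1, x, NA), r = r)
d
#> Incomplete dataset: n = 300 , complete cases n1 = 214

imps <- multiply_impute(d, method = "jav", M = 5)
fits <- lapply(imps, function(z) fit_quadratic_ols(z$y, z$x, z$derived))
pool_fits(fits)
#> Rubin-pooled estimate 1.2981 (total var 0.07223 = within 0.06339 + (1+1/5)*between 0.007369)
#>   df = 266.89, 95% CI [0.7689, 1.8272]
```

The pooled quadratic coefficient (true value 1) is 1.30 with a 95% CI
[0.77, 1.83]: the interval covers the truth, and the between-imputation
variance term shows how much uncertainty the missing 86 X values add.

A small simulation cell (200 replicates here; the full evaluation uses
1000) compares all methods at once:

```r
cfg <- scenario_config("quadratic", "normal", mechanism = "MCAR",
                       r_squared = 0.5, reps = 200, seed = 1)
summarize_replicates(run_scenario(cfg))
#>    method bias_pct coverage_pct rel_precision_pct mcse_bias_pct ...
#> 1   cdata    0.048           94               100           2.4
#> 2   ccase   -4.387           94                70           2.8
#> 3 passive  -23.063           96               120           2.2
#> 4     pmm   -4.162           94                67           2.9
#> 5     jav   -4.075           94                66           2.9
```

Read: passive imputation underestimates the quadratic effect by ~23%
(within ~1 MCSE of its published attenuation), while PMM and JAV are near
the complete-case reference; `rel_precision_pct` is the complete-data
variance relative to each method (complete cases retain ~70% precision at
70% observation), and `mcse_bias_pct` is the Monte-Carlo standard error of
the bias.

A command-line front end `exec/mi-nonlin` wraps the same functions
(`mi-nonlin gen|impute|simulate`, YAML scenario configs, CSV data with
blank cells for missing X; see `inst/extdata/scenario-quadratic-mar.yaml`).

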