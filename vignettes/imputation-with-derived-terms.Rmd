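---
title: "Imputing a covariate that appears twice: passive, PMM and JAV"
author: "minonlin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing a covariate that appears twice: passive, PMM and JAV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epidemiological analysis models often contain more than one function of the
same covariate: a quadratic term to capture curvature (`Y ~ X + X^2`) or an
interaction with a second exposure (`Y ~ X + Z + XZ`).  When `X` has missing
values, multiple imputation (MI) must somehow respect — or deliberately
ignore — the functional link between `X` and the derived term.  `minonlin`
implements the three strategies that standard MI software makes easy, and a
simulation harness for measuring how badly each one can go wrong.
Throughout, `Y` (and `Z`) are fully observed, only `X` is incomplete, and
`R_i = 1` indicates that `X_i` was observed (`n1` complete cases).

## The three imputation methods

**Passive imputation** ("impute then transform").  A linear imputation
model `X ~ N(gamma' W, sigma^2)` is fitted to the complete cases, where `W`
is `(1, Y)` for the quadratic analyses and `(1, Y, Z)` (optionally plus
`YZ`) for the interaction analyses.  With the noninformative prior
proportional to `1/sigma^2`, the posterior gives

* `sigma*^2 = (n1 - q) sigma2_hat / chisq(n1 - q)`, with `sigma2_hat` the
  unbiased residual variance (divisor `n1 - q`), and
* `gamma* ~ N(gamma_hat, psi sigma*^2)` with `psi = (W'W)^{-1}` over
  complete cases.

Missing `X_i` are imputed as `gamma*' W_i + sigma* B_i`, `B_i ~ N(0,1)`, and
the derived term is then *computed* from the imputed value, so
`derived = x^2` (or `xz`) holds exactly on every row.  The weakness is that
the linear imputation model for `X | Y` is misspecified whenever the
quadratic or interaction effect is nonzero, which attenuates the estimated
effect.

**Predictive mean matching (PMM)** shares the fit and the posterior draw,
but uses the perturbed fitted values `Xhat*_i = gamma*' W_i` only for
matching: each incomplete case borrows the observed `X` of one of the `K`
complete cases with the nearest fitted value, chosen uniformly at random.
Every imputed value has therefore been realised in the data.  `K = 5`
balances matching tightness (bias) against imputation variability
(interval width).  Because the fitted values come from the perturbed draw,
the donor pool varies across imputations.  With the single predictor `Y`,
matching on fitted values is matching on `Y` itself.

**JAV** ("just another variable", or "transform then impute") treats the
derived term as an unrelated variable and assumes `(Y, X, X^2)` — or
`(Y, X, Z, XZ)` — is jointly multivariate normal.  Since `Y` (and `Z`) are
complete, it suffices to fit the conditional bivariate regression of the
pair `(X, derived)` on `W` among complete cases and impute the pair jointly
from the conditional normal.  The imputed pair need not satisfy
`derived = x^2`; that incoherence is intentional, because the analysis-model
parameters depend on the joint moments of `(Y, X, derived)` only, and under
MCAR the complete-case moments estimate the population moments
consistently.  Under MAR they do not (the complete cases are a biased
sample for the *least-false* multivariate-normal parameters), so JAV is
consistent under MCAR but generally biased under MAR — the property the
simulation harness quantifies.

The JAV parameter perturbation is stated in the literature only as "similar
to" the univariate recipe; we use the standard noninformative
multivariate-regression posterior, its direct generalisation: `tau*` is
inverse-Wishart with `n1 - q` degrees of freedom and scale the residual
sum-of-cross-products matrix (in one dimension this is exactly the scaled
inverse-chi-squared above), and `delta*` is matrix-normal with row
covariance `psi` and column covariance `tau*`.  Acceptance-level agreement
with the published tables confirms the choice is not load-bearing.

After imputation, the analysis model (OLS for the linear designs, logistic
ML for the binary design) is fitted to each of the `M = 5` completed
datasets and the target coefficient pooled by **Rubin's Rules**: estimate
the mean, total variance `W + (1 + 1/M) B`, and the classic 1987 degrees of
freedom `(M-1)(1 + W/((1+1/M)B))^2`.  We deliberately use the 1987 df, not
the Barnard–Rubin small-sample correction; at `M = 5`, `n = 200` the
difference in coverage is below about one percentage point, and the choice
is recorded in every report sidecar so sensitivity can be assessed.

## The simulation designs

`scenario_config()` encodes the classical evaluation grid:

* **Covariates.** Four families, each with mean 2 and variance 1: normal;
  log-normal (`log X ~ N(log(3.2)/2, log(5/4))`, the unique log-normal with
  these moments, skewness 1.63); shifted/scaled beta
  (`12.05 (B - 1/11) + 2`, `B ~ Beta(1,10)`, skewness 1.51); and uniform
  `U(2 - sqrt(3), 2 + sqrt(3))`, the unique uniform with these moments (the
  bounds are forced by the moment constraints).  Bivariate designs impose
  correlation 0.5 on the natural scale (normal) or the log scale
  (log-normal).
* **Outcomes.** `Y ~ N(2X + X^2, phi)`, `Y ~ N((X-2)^2, phi)`,
  `Y ~ N(X + Z + XZ, phi)`, or binary
  `P(Y=1|X) = expit(beta0 + 2 beta2 X + beta2 X^2)` with
  `beta2 in {1/12, 1/6}` (log odds ratio 1 or 2 comparing `X = 3` with
  `X = 1`, i.e. mean ± one SD for normal `X`).
* **Missingness.** `X` observed with probability `expit(alpha0 + alpha1 Y)`;
  `alpha1 = 0` (MCAR), `-1/SD(Y)` (linear MAR) or `-2` (logistic MAR).
* **Scale.** `n = 200` (linear) or `2000` (logistic), 1000 replicates,
  `M = 5`, `K = 5`, 70% of `X` observed.

Three nuisance constants are fixed only implicitly by the designs and are
calibrated by `calibrate_scenario()`:

* `phi = Var(m(X)) (1 - R^2)/R^2` reaches the target R-squared.  For the
  normal family `Var(2X + X^2) = 38` and `Var((X-2)^2) = 2` in closed form;
  other families use a fixed-seed 10^6-draw Monte-Carlo moment.
* `beta0` solves `E[expit(beta0 + 2 beta2 X + beta2 X^2)] = p` by bracketed
  root finding over a fixed-seed 10^6-draw covariate sample.
* `alpha0` solves `E[expit(alpha0 + alpha1 Y)] = 0.7` over a fixed-seed
  population-scale sample of `Y`; `SD(Y)` in the MAR slope is likewise the
  population value `sqrt(Var(m) + phi)`.

All three are computed once per scenario from fixed-seed population
samples and shared across replicates.  Calibrating per replicate would
subtly change the estimand (the mechanism would depend on the realised
sample), so the constants are treated as part of the design, not as data.
For the logistic designs the mechanism text nominally conditions on
observing *Y*, but `Y` is complete by construction; it is read as the
observation probability of `X`.  With binary `Y`, JAV simply treats `Y` as
a numeric predictor in the conditional-normal fit — the multivariate-normal
model is already deliberately misspecified, which is exactly the behaviour
under study.

Replicate-level random-number streams are derived deterministically from
`(master seed, replicate index, method)`, so runs are exactly reproducible
and adding a method to the grid leaves the other methods' draws unchanged.

## Metrics

`summarize_replicates()` reports, per method: percent bias
`100 (mean(estimate) - true)/|true|` (true value 1 for the linear designs,
`beta2` for the logistic), empirical coverage of the nominal 95% intervals,
relative precision `100 var(complete-data estimates)/var(method estimates)`,
and Monte-Carlo standard errors.  Replicates where the logistic ML fit
fails (non-convergence, separation, a degenerate outcome) are excluded from
that method's summaries and counted in `n_failed`; at `n = 2000` these are
rare.

## Numerical choices and edge cases

* Linear fits use QR decompositions; rank-deficient designs raise an error
  (reference analyses) or mark the replicate failed (inside the harness).
  Logistic ML runs IRLS with tolerance 1e-8 and at most 100 iterations;
  CIs use `t` quantiles with residual df for OLS and normal quantiles for
  logistic fits.
* A numerically singular residual cross-product matrix in the JAV fit
  (possible at tiny `n1`) is ridged by 1e-10 on the diagonal with a
  warning before Wishart sampling.
* PMM ties in the matching distance are broken by randomly permuting the
  complete cases before a stable sort; with fewer than `K` complete cases
  the donor pool degenerates to all of them.
* `sigma2_hat = 0` (an exactly linear complete-case relation) collapses the
  posterior draw to the MLE rather than erroring.
* Rubin df is `Inf` when the between-imputation variance is zero.

## What the generator does and does not emulate

The generator reproduces the evaluation designs exactly: known functional
form of the outcome model, a single incomplete covariate with a monotone
missingness pattern driven by the observed outcome only, and homoskedastic
linear errors.  Because missingness is monotone in one variable, no
chained-equations iteration is needed or implemented.  Real data differ in
ways these simulations deliberately exclude: heteroskedasticity (which can
reverse the qualitative ranking of the methods), missingness in several variables at once, auxiliary variables,
MNAR mechanisms, and categorical incomplete covariates.  Passing the
simulation suite therefore certifies the estimators under the stated
designs, not robust behaviour on arbitrary real datasets.

## Problem sizes used in the tests

The acceptance-level checks run the full published scale — 1000 replicates
at `n = 200` (linear) or `n = 2000` (logistic) per cell, plus a 500-replicate
`n = 5000` run for the MCAR consistency property — which completes in a few
minutes on one CPU.  Unit tests use 10^4–10^6 draws for distributional
checks and small fixtures elsewhere.  The interaction designs support all
three R-squared columns (0.1, 0.5, 0.8) even though the narrative text
mentions only two; both are accepted by `scenario_config()`.

## Known limitations

* Single incomplete covariate; no missingness in `Y` or `Z`.
* No robust (sandwich) variance estimator; classical covariances only.
* Scalar pooling only (the target coefficient), not vector Wald tests.
* The JAV perturbation is one reasonable posterior among the "similar"
  family; Monte-Carlo-level tolerances absorb the difference.
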