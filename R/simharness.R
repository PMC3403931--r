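# Simulation harness: scenario configuration, calibration of the scenario
# constants (phi, beta0, alpha0), replicate generation, per-method
# estimation, and the bias/coverage/relative-precision summaries.

.ALL_METHODS <- c("cdata", "ccase", "passive", "passive2", "pmm", "jav")

.outcome_kind <- function(analysis) {
  switch(analysis,
         quadratic          = "linear_quadratic",
         quadratic_centered = "linear_quadratic_centered",
         interaction        = "linear_interaction",
         logistic           = "logistic_quadratic")
}

# The imputers only distinguish quadratic-style (derived = X^2) from
# interaction-style (derived = XZ) completion.
.mi_analysis <- function(analysis) {
  if (analysis == "interaction") "interaction" else "quadratic"
}

#' Configure a simulation scenario
#'
#' A scenario fixes the analysis model, the covariate distribution, the
#' missingness mechanism, the signal strength (R-squared for linear
#' analyses; marginal outcome probability and beta2 for the logistic
#' analysis), the sample size, and the Monte-Carlo settings.
#'
#' @param analysis `"quadratic"` (Y ~ N(2X + X^2, phi)),
#'   `"quadratic_centered"` (Y ~ N((X-2)^2, phi)), `"interaction"`
#'   (Y ~ N(X + Z + XZ, phi)) or `"logistic"`
#'   (P(Y=1|X) = expit(beta0 + 2*beta2*X + beta2*X^2)).
#' @param x_dist covariate family, see [covariate_spec()].
#' @param correlation X-Z correlation for bivariate designs.
#' @param mechanism `"MCAR"` or `"MAR"`.  MAR observes X with probability
#'   `expit(alpha0 + alpha1*Y)` where `alpha1 = -1/SD(Y)` for linear
#'   analyses and `alpha1 = -2` for the logistic analysis.
#' @param r_squared target R-squared (linear analyses).
#' @param marginal_p,beta2 marginal `P(Y = 1)` and quadratic coefficient
#'   (logistic analysis).
#' @param n sample size per replicate; defaults to 200 (linear) or 2000
#'   (logistic).
#' @param reps number of simulated datasets.
#' @param M,K number of imputations and PMM donor pool size.
#' @param methods subset of `c("cdata", "ccase", "passive", "passive2",
#'   "pmm", "jav")`; `"passive2"` (passive with the YZ term in the
#'   imputation model) is only valid for interaction analyses.
#' @param seed master seed; replicate- and method-level streams are derived
#'   from it deterministically.
#' @param target_obs marginal probability that X is observed (0.7 in the
#'   classical designs; 1 disables missingness).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(analysis = c("quadratic", "quadratic_centered",
                                         "interaction", "logistic"),
                            x_dist = "normal", correlation = 0,
                            mechanism = c("MCAR", "MAR"),
                            r_squared = NULL, marginal_p = NULL, beta2 = NULL,
                            n = NULL, reps = 1000L, M = 5L, K = 5L,
                            methods = NULL, seed = 1L, target_obs = 0.7) {
  analysis <- match.arg(analysis)
  mechanism <- match.arg(mechanism)
  spec <- covariate_spec(x_dist, correlation)
  if (is.null(n)) n <- if (analysis == "logistic") 2000L else 200L
  if (is.null(methods))
    methods <- if (analysis == "interaction") .ALL_METHODS
               else setdiff(.ALL_METHODS, "passive2")
  stopifnot(n >= 20, reps >= 1, M >= 2, K >= 1,
            all(methods %in% .ALL_METHODS))
  if ("passive2" %in% methods && analysis != "interaction")
    stop("passive2 is only defined for interaction analyses")
  if (analysis == "logistic") {
    if (is.null(marginal_p) || is.null(beta2))
      stop("logistic scenarios require marginal_p and beta2")
  } else if (is.null(r_squared)) {
    stop("linear scenarios require r_squared")
  }
  if (target_obs <= 0 || target_obs > 1)
    stop("target_obs must lie within (0, 1]")
  structure(list(analysis = analysis, spec = spec, mechanism = mechanism,
                 r_squared = r_squared, marginal_p = marginal_p,
                 beta2 = beta2, n = as.integer(n), reps = as.integer(reps),
                 M = as.integer(M), K = as.integer(K), methods = methods,
                 seed = as.integer(seed), target_obs = target_obs),
            class = "scenario_config")
}

#' Calibrate the scenario constants
#'
#' Computes the nuisance constants the designs fix implicitly: the residual
#' variance `phi` reaching the target R-squared (linear), the logistic
#' intercept `beta0` reaching the target marginal outcome probability, and
#' the missingness intercept `alpha0` reaching the target observation
#' probability.  All use fixed-seed population-scale (10^6) samples, so they
#' are scenario constants shared across replicates rather than per-replicate
#' quantities; `SD(Y)` entering the linear MAR slope `alpha1 = -1/SD(Y)` is
#' likewise the population value `sqrt(Var(m(X)) + phi)`.
#'
#' @param config a [scenario_config()].
#' @param n_mc calibration sample size.
#' @param calib_seed fixed seed for the calibration samples.
#' @return an object of class `scenario_calibration` with elements `phi`,
#'   `beta0`, `alpha0`, `alpha1`, `sd_y`, `var_m`, `true_value`.
#' @export
calibrate_scenario <- function(config, n_mc = 1e6, calib_seed = 60901L) {
  stopifnot(inherits(config, "scenario_config"))
  spec <- config$spec
  if (config$analysis == "logistic") {
    beta0 <- calibrate_logistic_intercept(config$beta2, spec,
                                          config$marginal_p, n_mc, calib_seed)
    alpha1 <- if (config$mechanism == "MAR") -2 else 0
    y_ref <- local_seed(calib_seed + 1L, {
      x <- make_covariates(spec, n_mc)
      make_binary_outcome(x, beta0, config$beta2)
    })
    alpha0 <- calibrate_missingness_intercept(alpha1, y_ref,
                                              config$target_obs)
    out <- list(phi = NA_real_, beta0 = beta0, alpha0 = alpha0,
                alpha1 = alpha1, sd_y = sd(y_ref), var_m = NA_real_,
                true_value = config$beta2)
  } else {
    kind <- .outcome_kind(config$analysis)
    phi <- calibrate_noise_variance(kind, spec, config$r_squared,
                                    n_mc, calib_seed)
    var_m <- phi * config$r_squared / (1 - config$r_squared)
    sd_y <- sqrt(var_m + phi)
    alpha1 <- if (config$mechanism == "MAR") -1 / sd_y else 0
    alpha0 <- if (alpha1 == 0) {
      calibrate_missingness_intercept(0, numeric(0), config$target_obs)
    } else {
      y_ref <- local_seed(calib_seed + 1L, {
        if (config$analysis == "interaction") {
          xz <- make_covariates(spec, n_mc, bivariate = TRUE)
          make_linear_outcome(xz[, 1], kind, phi, xz[, 2])
        } else {
          make_linear_outcome(make_covariates(spec, n_mc), kind, phi)
        }
      })
      calibrate_missingness_intercept(alpha1, y_ref, config$target_obs)
    }
    out <- list(phi = phi, beta0 = NA_real_, alpha0 = alpha0,
                alpha1 = alpha1, sd_y = sd_y, var_m = var_m,
                true_value = 1)
  }
  structure(c(out, list(n_mc = n_mc, calib_seed = calib_seed)),
            class = "scenario_calibration")
}

#' Generate one simulated replicate
#'
#' Draws covariates, the outcome, and the observation indicator under the
#' scenario's mechanism, using the current RNG stream.  The pre-deletion
#' covariate is retained in `x_true` for the complete-data reference.
#'
#' @param config a [scenario_config()].
#' @param calib a matching [calibrate_scenario()] result.
#' @return an [incomplete_dataset()].
#' @export
generate_replicate <- function(config, calib) {
  z <- NULL
  if (config$analysis == "interaction") {
    xz <- make_covariates(config$spec, config$n, bivariate = TRUE)
    x <- xz[, 1]
    z <- xz[, 2]
  } else {
    x <- make_covariates(config$spec, config$n)
  }
  y <- if (config$analysis == "logistic") {
    make_binary_outcome(x, calib$beta0, config$beta2)
  } else {
    make_linear_outcome(x, .outcome_kind(config$analysis), calib$phi, z)
  }
  r <- apply_missingness(y, calib$alpha0, calib$alpha1)
  x_obs <- ifelse(r == 1L, x, NA_real_)
  incomplete_dataset(y = y, x = x_obs, r = r, z = z, x_true = x)
}

# Run one method on one replicate; never throws.  Returns estimate, SE and
# CI, or a failure row (logistic non-convergence, singular fits, ...).
run_method <- function(data, method, config) {
  fail <- list(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, failed = TRUE)
  if (method %in% c("cdata", "ccase")) {
    fit <- tryCatch(estimate_reference(data, method, config$analysis),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(fail)
    s <- target_summary(fit)
    return(list(estimate = s$estimate, se = s$se, ci_low = s$ci_low,
                ci_high = s$ci_high, failed = FALSE))
  }
  mi_method <- if (method == "passive2") "passive" else method
  preds <- if (method == "passive2") c("y", "z", "yz") else NULL
  imps <- tryCatch(
    multiply_impute(data, mi_method, M = config$M, K = config$K,
                    analysis = .mi_analysis(config$analysis),
                    predictors = preds),
    error = function(e) NULL)
  if (is.null(imps)) return(fail)
  fits <- lapply(imps, function(d) {
    tryCatch(switch(config$analysis,
                    logistic    = fit_logistic_quadratic(d$y, d$x, d$derived),
                    interaction = fit_interaction_ols(d$y, d$x, d$z, d$derived),
                    fit_quadratic_ols(d$y, d$x, d$derived)),
             error = function(e) NULL)
  })
  if (any(vapply(fits, is.null, TRUE)) ||
      any(!vapply(fits, `[[`, TRUE, "converged"))) return(fail)
  pr <- pool_fits(fits)
  list(estimate = pr$estimate, se = sqrt(pr$total_var),
       ci_low = pr$ci_low, ci_high = pr$ci_high, failed = FALSE)
}

#' Run a full simulation scenario
#'
#' For each replicate: generate covariates, outcome and missingness, then
#' run each requested method (imputing and pooling for the MI methods).
#' Replicate-level RNG streams are derived deterministically from the master
#' seed, per replicate and per method, so output is reproducible and adding
#' a method does not perturb the others' draws.  Per-replicate method
#' failures are recorded, not fatal.
#'
#' @param config a [scenario_config()].
#' @param calib optional pre-computed [calibrate_scenario()] result.
#' @param verbose print progress every 100 replicates?
#' @return a data frame with one row per (replicate, method):
#'   `rep`, `method`, `estimate`, `se`, `ci_low`, `ci_high`, `failed`;
#'   the calibration and config are attached as attributes.
#' @export
run_scenario <- function(config, calib = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(calib)) calib <- calibrate_scenario(config)
  nm <- length(config$methods)
  streams <- match(config$methods, .ALL_METHODS)
  rows <- vector("list", config$reps * nm)
  k <- 0L
  for (rep in seq_len(config$reps)) {
    set.seed(child_seed(config$seed, rep, 0L))
    data <- generate_replicate(config, calib)
    for (j in seq_len(nm)) {
      set.seed(child_seed(config$seed, rep, streams[j]))
      res <- run_method(data, config$methods[j], config)
      k <- k + 1L
      rows[[k]] <- c(rep, res$estimate, res$se, res$ci_low, res$ci_high,
                     as.numeric(res$failed))
    }
    if (verbose && rep %% 100L == 0L)
      message("replicate ", rep, "/", config$reps)
  }
  tab <- do.call(rbind, rows)
  out <- data.frame(rep = as.integer(tab[, 1]),
                    method = rep(config$methods, times = config$reps),
                    estimate = tab[, 2], se = tab[, 3],
                    ci_low = tab[, 4], ci_high = tab[, 5],
                    failed = tab[, 6] == 1)
  attr(out, "calibration") <- calib
  attr(out, "config") <- config
  out
}

#' Summarise replicate-level results into the evaluation metrics
#'
#' Per method: percent bias `100 * (mean(estimate) - true) / |true|`,
#' empirical coverage of the nominal 95% intervals, relative precision
#' `100 * var(cdata estimates) / var(method estimates)` (NA when the
#' complete-data reference was not run), and Monte-Carlo standard errors of
#' the bias and coverage.  Failed replicates are excluded and counted.
#'
#' @param results a [run_scenario()] data frame.
#' @param true_value true value of the target coefficient; defaults to the
#'   attached calibration's value.
#' @return a data frame of class `mi_metrics`, one row per method with
#'   columns `method`, `bias_pct`, `coverage_pct`, `rel_precision_pct`,
#'   `mcse_bias_pct`, `mcse_coverage_pct`, `n_used`, `n_failed`.
#' @export
summarize_replicates <- function(results, true_value = NULL) {
  if (is.null(true_value)) {
    calib <- attr(results, "calibration")
    if (is.null(calib)) stop("true_value not supplied and no calibration attached")
    true_value <- calib$true_value
  }
  methods <- unique(results$method)
  cdata_var <- NA_real_
  if ("cdata" %in% methods) {
    e <- results$estimate[results$method == "cdata" & !results$failed]
    if (length(e) >= 2L) cdata_var <- var(e)
  }
  out <- lapply(methods, function(m) {
    sub <- results[results$method == m, , drop = FALSE]
    ok <- !sub$failed & is.finite(sub$estimate)
    nr <- sum(ok)
    if (nr < 2L)
      return(data.frame(method = m, bias_pct = NA_real_,
                        coverage_pct = NA_real_,
                        rel_precision_pct = NA_real_,
                        mcse_bias_pct = NA_real_,
                        mcse_coverage_pct = NA_real_,
                        n_used = nr, n_failed = sum(!ok)))
    est <- sub$estimate[ok]
    cover <- mean(sub$ci_low[ok] <= true_value & true_value <= sub$ci_high[ok])
    p <- cover
    data.frame(
      method = m,
      bias_pct = 100 * (mean(est) - true_value) / abs(true_value),
      coverage_pct = 100 * cover,
      rel_precision_pct = 100 * cdata_var / var(est),
      mcse_bias_pct = 100 * sd(est) / (abs(true_value) * sqrt(nr)),
      mcse_coverage_pct = 100 * sqrt(p * (1 - p) / nr),
      n_used = nr, n_failed = sum(!ok))
  })
  out <- do.call(rbind, out)
  class(out) <- c("mi_metrics", "data.frame")
  attr(out, "true_value") <- true_value
  out
}

#' Write a scenario report
#'
#' Writes the metrics table as CSV plus a JSON sidecar recording the
#' configuration, the master seed and the calibrated scenario constants
#' (phi, beta0, alpha0, alpha1, SD(Y)) and pooling conventions, so a cell
#' can be audited or re-run.
#'
#' @param metrics a [summarize_replicates()] table.
#' @param config the [scenario_config()] that produced it.
#' @param calib the matching [calibrate_scenario()] result.
#' @param dir output directory (created if needed).
#' @param stem file stem; writes `<stem>.csv` and `<stem>.json`.
#' @return invisibly, the paths written.
#' @export
write_report <- function(metrics, config, calib, dir, stem = "metrics") {
  stopifnot(nrow(metrics) >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  json <- file.path(dir, paste0(stem, ".json"))
  write.csv(as.data.frame(metrics), csv, row.names = FALSE)
  sidecar <- list(
    config = list(analysis = config$analysis,
                  x_dist = config$spec$family,
                  correlation = config$spec$correlation,
                  mechanism = config$mechanism,
                  r_squared = config$r_squared,
                  marginal_p = config$marginal_p, beta2 = config$beta2,
                  n = config$n, reps = config$reps, M = config$M,
                  K = config$K, methods = config$methods,
                  seed = config$seed, target_obs = config$target_obs),
    calibration = list(phi = calib$phi, beta0 = calib$beta0,
                       alpha0 = calib$alpha0, alpha1 = calib$alpha1,
                       sd_y = calib$sd_y, true_value = calib$true_value,
                       n_mc = calib$n_mc, calib_seed = calib$calib_seed),
    software = list(pooling_df = "rubin1987",
                    linear_ci = "t", logistic_ci = "wald-normal"))
  jsonlite::write_json(sidecar, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(csv = csv, json = json))
}
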