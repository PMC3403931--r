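# Plain-text interfaces: YAML scenario configs, one-replicate CSVs with
# blank cells for missing X, and long-format multiply-imputed CSVs.

#' Read a scenario configuration from YAML (or JSON)
#'
#' The file holds the arguments of [scenario_config()] as top-level keys,
#' e.g. `analysis: quadratic`, `x_dist: normal`, `mechanism: MAR`,
#' `r_squared: 0.5`, `n: 200`, `reps: 1000`, `M: 5`, `K: 5`, `seed: 1`.
#'
#' @param path file path.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  # keep bare keys like `n` as strings instead of YAML 1.1 booleans
  keep <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  vals <- yaml::read_yaml(path, handlers = keep)
  known <- names(formals(scenario_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(scenario_config, vals)
}

#' Write and read one replicate as CSV
#'
#' Columns `y`, `x` and (if present) `z`, with empty cells marking missing
#' `x` values.
#'
#' @param data an [incomplete_dataset()].
#' @param path file path.
#' @return `write_incomplete_csv` returns `path` invisibly;
#'   `read_incomplete_csv` returns an [incomplete_dataset()].
#' @export
write_incomplete_csv <- function(data, path) {
  df <- data.frame(y = data$y, x = data$x)
  if (!is.null(data$z)) df$z <- data$z
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_incomplete_csv
#' @export
read_incomplete_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("y", "x") %in% names(df)))
    stop("CSV must contain columns y and x")
  incomplete_dataset(y = df$y, x = df$x,
                     z = if ("z" %in% names(df)) df$z else NULL)
}

#' Write multiply imputed data in long format
#'
#' One block per imputation with an imputation-index column `imp`:
#' `imp = 0` is the original data with blanks for missing `x`, and
#' `imp = 1..M` are the completed datasets including the imputed derived
#' term (`xsq` or `xz` column).
#'
#' @param imps list of completed datasets from [multiply_impute()].
#' @param data the original [incomplete_dataset()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_imputed_long <- function(imps, data, path) {
  derived_name <- if (is.null(data$z)) "xsq" else "xz"
  block <- function(imp, y, x, z, derived) {
    df <- data.frame(imp = imp, id = seq_along(y), y = y, x = x)
    if (!is.null(z)) df$z <- z
    df[[derived_name]] <- derived
    df
  }
  out <- block(0L, data$y, data$x, data$z, rep(NA_real_, data$n))
  for (m in seq_along(imps)) {
    d <- imps[[m]]
    out <- rbind(out, block(m, d$y, d$x, d$z, d$derived))
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
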