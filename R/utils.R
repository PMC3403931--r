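#' Inverse-logit and logit
#'
#' `expit(x)` is `1/(1 + exp(-x))`; `logit(p)` is its inverse.  Used
#' throughout for missingness mechanisms and logistic outcome models.
#'
#' @param x,p numeric vectors.
#' @return numeric vector.
#' @export
expit <- function(x) plogis(x)

#' @rdname expit
#' @export
logit <- function(p) qlogis(p)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  Calibration routines use this so that
# scenario constants are deterministic and do not perturb simulation draws.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for (master seed, replicate, stream).  Streams
# separate the data-generation draws from each method's imputation draws so
# adding a method does not perturb the others.
child_seed <- function(master, replicate, stream = 0L) {
  as.integer((as.double(master) * 48271 + replicate * 1009 +
                stream * 97 + 11) %% 2147483629)
}

# Design matrix for the imputation model: intercept plus any of Y, Z, YZ.
design_matrix <- function(data, predictors) {
  bad <- setdiff(predictors, c("y", "z", "yz"))
  if (length(bad))
    stop("unknown imputation predictors: ", paste(bad, collapse = ", "))
  n <- length(data$y)
  cols <- list(rep(1, n))
  names(cols) <- "(Intercept)"
  for (p in predictors) {
    if (p %in% c("z", "yz") && is.null(data$z))
      stop("predictor '", p, "' requires a z column")
    cols[[p]] <- switch(p, y = data$y, z = data$z, yz = data$y * data$z)
  }
  do.call(cbind, cols)
}
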