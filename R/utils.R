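#' @keywords internal
"_PACKAGE"

#' @useDynLib adnapop, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rpois runif rbeta pchisq coef median optimize var
#' @importFrom utils head tail
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Weighted delete-one-block jackknife (Busing-style): `full` is the all-block
# estimate, `loo` the delete-one estimates, `weights` the block sizes.
weighted_jackknife <- function(full, loo, weights) {
  g <- length(loo)
  stopifnot(length(weights) == g, g >= 2)
  n <- sum(weights)
  h <- n / weights
  theta_j <- g * full - sum((1 - weights / n) * loo)
  tau <- h * full - (h - 1) * loo
  se <- sqrt(sum((tau - theta_j)^2 / (h - 1)) / g)
  list(est = full, se = se, bias_corrected = theta_j)
}

# Jackknife covariance matrix of a vector statistic: rows of `loo` are the
# delete-one-block estimates, `full` the all-block estimate.
weighted_jackknife_cov <- function(full, loo, weights) {
  g <- nrow(loo)
  n <- sum(weights)
  h <- n / weights
  tau <- -(h - 1) * loo + outer(h, full)
  tau_bar <- colMeans(tau)
  tc <- sweep(tau, 2, tau_bar)
  crossprod(tc / sqrt((h - 1))) / g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
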