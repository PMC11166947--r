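corner_mask <- function(a) {
  # TRUE for the two fixed (non-segregating) corner cells
  m <- array(FALSE, dim(a))
  m[matrix(1, 1, length(dim(a)))] <- TRUE
  m[matrix(dim(a), 1)] <- TRUE
  m
}

#' Multinomial composite log-likelihood of an observed joint SFS
#'
#' \eqn{\sum_k n_k \log \hat p_k} over segregating cells, with the
#' expected probabilities floored at `1e-12` (floored cells are counted
#' and reported in a warning). Monomorphic corner cells are excluded.
#'
#' @param observed observed `joint_sfs` (counts).
#' @param expected expected `joint_sfs` (probabilities, from
#'   [expected_sfs()]).
#' @return The composite log-likelihood (scalar).
#' @export
composite_loglik <- function(observed, expected) {
  if (!identical(dim(observed), dim(expected)))
    stop("observed and expected SFS dimensions differ")
  keep <- !corner_mask(observed)
  n <- as.numeric(observed)[keep]
  p <- as.numeric(expected)[keep]
  floored <- n > 0 & p < 1e-12
  if (any(floored))
    warning(sum(floored), " observed cell(s) had expected probability ",
            "< 1e-12 (floored)")
  sum(n * log(pmax(p, 1e-12)))
}

#' Single-parameter profile fit of a demographic model to a joint SFS
#'
#' For each grid value of one parameter (all others held fixed), computes
#' the Monte-Carlo expected SFS with common random numbers (the same seed
#' for every grid point, so Monte-Carlo noise largely cancels across the
#' profile) and the multinomial composite log-likelihood of the observed
#' SFS; returns the profile maximum, refined by a quadratic interpolation
#' through the argmax and its neighbors (on the log scale for geometric
#' grids).
#'
#' @param model a [demography_model()].
#' @param param parameter path (see [set_parameter()]).
#' @param grid sorted numeric grid (>= 5 points).
#' @param observed observed `joint_sfs` counts.
#' @param n_reps genealogies per expected-SFS evaluation.
#' @param seed integer seed (shared across grid points).
#' @param scale `"linear"` or `"log"`: grid geometry for the quadratic
#'   refinement.
#' @return A `profile_fit`: `param`, `grid`, `loglik`, `estimate`,
#'   `estimate_grid` (unrefined argmax), `unidentifiable` flag.
#' @export
fit_parameter_profile <- function(model, param, grid, observed,
                                  n_reps = 20000, seed = 1,
                                  scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (length(grid) < 5) stop("grid must have at least 5 points")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be sorted, unique")
  # grid values that violate the model's event ordering (e.g. a split time
  # moved past a fixed pulse) have zero likelihood
  expected <- lapply(grid, function(v)
    tryCatch(expected_sfs(set_parameter(model, param, v), n_reps = n_reps,
                          seed = seed),
             error = function(e) {
               message("grid value ", v, " invalid: ", conditionMessage(e))
               NULL
             }))
  ll <- vapply(expected, function(e)
    if (is.null(e)) -Inf else composite_loglik(observed, e), 0)
  if (sum(is.finite(ll)) < 3)
    stop("fewer than 3 valid grid points for ", param)
  profile_from_loglik(param, grid, ll, scale)
}

profile_from_loglik <- function(param, grid, ll, scale) {
  i <- which.max(ll)
  est <- grid[i]
  fin <- is.finite(ll)
  unident <- (max(ll[fin]) - min(ll[fin])) < 1e-6
  if (unident)
    warning("flat profile for ", param, ": parameter unidentifiable ",
            "from the sampled populations")
  if (!unident && i > 1 && i < length(grid) &&
      is.finite(ll[i - 1]) && is.finite(ll[i + 1])) {
    x <- if (scale == "log") log(grid[(i - 1):(i + 1)])
         else grid[(i - 1):(i + 1)]
    y <- ll[(i - 1):(i + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
          x[1] * (y[3] - y[2])) / denom
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / denom
    if (a < 0) {
      v <- -b / (2 * a)
      if (v >= x[1] && v <= x[3])
        est <- if (scale == "log") exp(v) else v
    }
  }
  structure(list(param = param, grid = grid, loglik = ll, estimate = est,
                 estimate_grid = grid[i], unidentifiable = unident),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("<profile_fit> %s = %.6g (grid argmax %.6g over %d points)%s\n",
              x$param, x$estimate, x$estimate_grid, length(x$grid),
              if (x$unidentifiable) " [unidentifiable]" else ""))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap 95%% CI [%.6g, %.6g] (n_boot %d)\n",
                x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' Nonparametric bootstrap confidence interval for a profile fit
#'
#' Resamples the site-level data (each site's SFS cell index) with
#' replacement, re-tallies the observed SFS and re-maximizes the profile.
#' The expensive expected-SFS grid is computed once and shared by all
#' bootstrap replicates, since it depends only on the model. Percentile
#' 2.5/97.5% bounds are reported.
#'
#' @inheritParams fit_parameter_profile
#' @param cells per-site flattened SFS cell indices (`cells` element of
#'   [simulate_coalescent()] output).
#' @param n_boot bootstrap replicates.
#' @return A `profile_fit` with `ci`, `boot_estimates`, `n_boot` added.
#' @export
bootstrap_ci <- function(model, param, grid, cells, n_reps = 20000,
                         n_boot = 100, seed = 1,
                         scale = c("linear", "log")) {
  scale <- match.arg(scale)
  sch <- coalescent_schedule(model)
  observed <- sfs_from_cells(cells, sch)
  expected <- lapply(grid, function(v)
    tryCatch(expected_sfs(set_parameter(model, param, v), n_reps = n_reps,
                          seed = seed),
             error = function(e) NULL))
  ll <- vapply(expected, function(e)
    if (is.null(e)) -Inf else composite_loglik(observed, e), 0)
  fit <- profile_from_loglik(param, grid, ll, scale)

  logp <- lapply(expected, function(e) {
    if (is.null(e)) return(NULL)
    log(pmax(as.numeric(e), 1e-12))
  })
  boot_est <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      res <- sample(cells, length(cells), replace = TRUE)
      cnt <- tabulate(res + 1L, nbins = sch$n_cells)
      llb <- vapply(logp, function(lp)
        if (is.null(lp)) -Inf else sum(cnt * lp), 0)
      pf <- suppressWarnings(profile_from_loglik(param, grid, llb, scale))
      pf$estimate
    }, 0)
  })
  failed <- !is.finite(boot_est)
  if (mean(failed) > 0.10)
    stop("more than 10% of bootstrap refits failed")
  fit$boot_estimates <- boot_est[!failed]
  fit$ci <- unname(stats::quantile(boot_est[!failed], c(0.025, 0.975)))
  fit$n_boot <- sum(!failed)
  fit
}

#' Export a profile fit as a JSON report
#'
#' @param fit a `profile_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(param = fit$param, grid = fit$grid, loglik = fit$loglik,
         estimate = fit$estimate, unidentifiable = fit$unidentifiable,
         ci = fit$ci, n_boot = fit$n_boot),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
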