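#' Weighted ancestry-covariance decay curve
#'
#' The admixture-LD dating statistic: SNPs are weighted by the source
#' allele-frequency contrast \eqn{w = p_1 - p_2}; per admixed individual
#' the residual at a SNP is the normalized genotype minus its expectation
#' \eqn{\bar p = \hat\alpha p_1 + (1 - \hat\alpha) p_2} (with
#' \eqn{\hat\alpha} the genome-wide least-squares mixture fraction of the
#' target on the two sources). For every within-chromosome SNP pair the
#' product \eqn{w_i w_j r_i r_j}, averaged over individuals, is assigned
#' to a genetic-distance bin; after a single pulse admixture the binned
#' curve decays as \eqn{\exp(-\lambda d)} with \eqn{\lambda} (per Morgan)
#' the age of the pulse in generations.
#'
#' @param geno admixed individuals, a [geno_matrix()] (diploid or
#'   pseudohaploid; pseudohaploid residuals use the single sampled allele).
#' @param source_freqs `pop_freq` with exactly two reference populations.
#' @param snp matching [snp_table()] (genetic positions in Morgans).
#' @param bin_min_cm,bin_max_cm,bin_step_cm distance-bin layout
#'   (left-closed bins); pairs closer than `bin_min_cm` are excluded as
#'   background-LD contaminated.
#' @param max_pairs_per_bin cap on pairs retained per bin per chromosome
#'   (deterministic seeded subsampling keeps runtime bounded).
#' @param seed seed for the pair subsampling.
#' @return A `decay_curve`: `data.frame` (bin_left_cm, bin_mid_cm, value,
#'   n_pairs; empty bins carry `NA`) with per-chromosome sums/counts in
#'   attributes for the delete-one-chromosome jackknife, and the estimated
#'   mixture fraction in attribute `alpha_hat`.
#' @export
ancestry_covariance <- function(geno, source_freqs, snp, bin_min_cm = 0.5,
                                bin_max_cm = 20, bin_step_cm = 0.1,
                                max_pairs_per_bin = 5e6, seed = 1) {
  if (length(source_freqs$populations) != 2)
    stop("source_freqs must hold exactly two reference populations")
  p1 <- source_freqs$freq[1, ]
  p2 <- source_freqs$freq[2, ]
  w <- p1 - p2
  # genome-wide mixture fraction by least squares on target mean frequency
  x <- colMeans(geno$values, na.rm = TRUE) / 2
  ok <- is.finite(x) & is.finite(w)
  alpha_hat <- sum((x - p2)[ok] * w[ok]) / sum(w[ok]^2)
  alpha_hat <- min(max(alpha_hat, 0), 1)
  pbar <- alpha_hat * p1 + (1 - alpha_hat) * p2

  edges <- seq(bin_min_cm, bin_max_cm, by = bin_step_cm)
  nbin <- length(edges) - 1
  chroms <- unique(snp$chromosome)
  sums <- matrix(0, length(chroms), nbin)
  cnts <- matrix(0, length(chroms), nbin)
  with_seed(seed, for (ci in seq_along(chroms)) {
    idx <- which(snp$chromosome == chroms[ci] & is.finite(w))
    if (length(idx) < 2) next
    R <- t(geno$values[, idx, drop = FALSE]) / 2 - pbar[idx]  # snp x ind
    R[is.na(R)] <- 0                        # missing calls contribute nothing
    U <- w[idx] * R
    P <- (U %*% t(U)) / nrow(geno$values)   # mean over individuals
    d_cm <- abs(outer(snp$genetic_pos[idx], snp$genetic_pos[idx], "-")) * 100
    ut <- upper.tri(P)
    b <- findInterval(d_cm[ut], edges, left.open = FALSE,
                      rightmost.closed = FALSE)
    vals <- P[ut]
    keep <- b >= 1 & b <= nbin
    b <- b[keep]; vals <- vals[keep]
    if (length(b) > max_pairs_per_bin * nbin) {
      sel <- sample(length(b), max_pairs_per_bin * nbin)
      b <- b[sel]; vals <- vals[sel]
    }
    rs <- rowsum(vals, b)
    sums[ci, as.integer(rownames(rs))] <- rs[, 1]
    cnts[ci, ] <- tabulate(b, nbins = nbin)
  })
  tot_cnt <- colSums(cnts)
  value <- ifelse(tot_cnt > 0, colSums(sums) / pmax(tot_cnt, 1), NA_real_)
  df <- data.frame(bin_left_cm = edges[-length(edges)],
                   bin_mid_cm = edges[-length(edges)] + bin_step_cm / 2,
                   value = value, n_pairs = tot_cnt)
  attr(df, "chrom_sums") <- sums
  attr(df, "chrom_counts") <- cnts
  attr(df, "chromosomes") <- chroms
  attr(df, "alpha_hat") <- alpha_hat
  class(df) <- c("decay_curve", "data.frame")
  df
}

curve_from_chroms <- function(curve, drop = NULL) {
  sums <- attr(curve, "chrom_sums")
  cnts <- attr(curve, "chrom_counts")
  keep <- setdiff(seq_len(nrow(sums)), drop)
  cnt <- colSums(cnts[keep, , drop = FALSE])
  data.frame(bin_mid_cm = curve$bin_mid_cm,
             value = ifelse(cnt > 0,
                            colSums(sums[keep, , drop = FALSE]) /
                              pmax(cnt, 1), NA_real_),
             n_pairs = cnt)
}

fit_decay_once <- function(df, fit_range) {
  sel <- df$bin_mid_cm >= fit_range[1] & df$bin_mid_cm <= fit_range[2] &
    is.finite(df$value) & df$n_pairs > 0
  if (sum(sel) < 5) stop("fewer than 5 non-empty bins in the fit range")
  d <- df$bin_mid_cm[sel] / 100   # Morgans
  y <- df$value[sel]
  # log-linear start on the positive part
  pos <- y > 0
  lam0 <- 10
  A0 <- max(y[1], 1e-6)
  if (sum(pos) >= 2) {
    fit0 <- stats::lm(log(y[pos]) ~ d[pos])
    if (is.finite(coef(fit0)[2]) && coef(fit0)[2] < 0) {
      lam0 <- -coef(fit0)[2]
      A0 <- exp(coef(fit0)[1])
    }
  }
  start <- c(A = unname(A0), lam = unname(lam0), c0 = 0)
  rss0 <- sum((y - start["A"] * exp(-start["lam"] * d))^2)
  if (rss0 < 1e-24 * max(sum(y^2), 1e-300))
    return(start)   # the log-linear start already fits to machine precision
  fit <- minpack.lm::nlsLM(y ~ A * exp(-lam * d) + c0,
                           start = as.list(start),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  coef(fit)
}

#' Fit an exponential to an ancestry-covariance decay curve
#'
#' Least-squares fit of \eqn{A_0 e^{-\lambda d} + c} over bin midpoints
#' (distances in Morgans). The decay rate \eqn{\lambda} per Morgan is the
#' time since admixture in generations; its standard error comes from a
#' delete-one-chromosome jackknife of the whole binning-and-fitting
#' pipeline.
#'
#' @param curve a `decay_curve` from [ancestry_covariance()].
#' @param fit_range `c(min_cM, max_cM)` distance range used in the fit.
#' @return A `date_fit`: `amplitude`, `lambda` (= generations `t_gens`),
#'   `baseline`, `se` (jackknife), `n_chrom`.
#' @export
fit_exponential <- function(curve, fit_range = c(0.5, 20)) {
  full <- tryCatch(fit_decay_once(curve, fit_range), error = function(e)
    stop("decay fit failed: ", conditionMessage(e)))
  nchr <- nrow(attr(curve, "chrom_sums"))
  loo <- rep(NA_real_, nchr)
  for (ci in seq_len(nchr)) {
    fit_i <- tryCatch(fit_decay_once(curve_from_chroms(curve, ci),
                                     fit_range), error = function(e) NULL)
    if (!is.null(fit_i)) loo[ci] <- fit_i["lam"]
  }
  loo <- loo[is.finite(loo)]
  if (length(loo) < 2) stop("too few chromosomes for a jackknife SE")
  g <- length(loo)
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  if (full["lam"] <= 0)
    stop("non-positive decay rate: no dateable admixture signal")
  structure(list(amplitude = unname(full["A"]),
                 lambda = unname(full["lam"]),
                 t_gens = unname(full["lam"]),
                 baseline = unname(full["c0"]), se = se, n_chrom = g),
            class = "date_fit")
}

#' @export
print.date_fit <- function(x, ...) {
  cat(sprintf("<date_fit> t = %.2f +/- %.2f generations (A0 %.3g, baseline %.3g, %d chromosomes)\n",
              x$t_gens, x$se, x$amplitude, x$baseline, x$n_chrom))
  invisible(x)
}

#' Convert an admixture date from generations to calendar years
#'
#' @param t_gens generations since admixture (> 0).
#' @param generation_time years per generation.
#' @param sample_age_years_ago age of the admixed samples.
#' @return A list: `years_before_sampling` = `t_gens * generation_time`;
#'   `years_ago` = that plus `sample_age_years_ago`.
#' @export
generations_to_years <- function(t_gens, generation_time = 29,
                                 sample_age_years_ago = 0) {
  if (t_gens <= 0) stop("t_gens must be positive")
  ybs <- t_gens * generation_time
  list(years_before_sampling = ybs,
       years_ago = ybs + sample_age_years_ago)
}
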