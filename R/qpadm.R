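# f4-matrix machinery for qpAdm: for lefts L (target first, then sources)
# and rights r1..rR, entry (l, j) is f4(l, r1; r_j, r1) for j = 2..R,
# estimated as a ratio of block sums with per-entry usable-SNP masks.
qpadm_blocks <- function(freqs, lefts, rights, blocks) {
  r1 <- freq_row(freqs, rights[1])
  nL <- length(lefts); nJ <- length(rights) - 1
  nsnp <- length(r1$p)
  bidx <- block_index(blocks, nsnp)
  nb <- nrow(blocks)
  S <- array(0, c(nb, nL, nJ))
  C <- array(0, c(nb, nL, nJ))
  lrows <- lapply(lefts, function(p) freq_row(freqs, p))
  rrows <- lapply(rights[-1], function(p) freq_row(freqs, p))
  for (l in seq_len(nL)) for (j in seq_len(nJ)) {
    terms <- (lrows[[l]]$p - r1$p) * (rrows[[j]]$p - r1$p)
    usable <- is.finite(terms)
    terms[!usable] <- 0
    S[, l, j] <- rowsum(terms, bidx, reorder = TRUE)
    C[, l, j] <- rowsum(as.numeric(usable), bidx, reorder = TRUE)
  }
  list(S = S, C = C, m = as.numeric(rowsum(rep(1, nsnp), bidx)))
}

# X estimates from block sums, optionally deleting block `drop`.
qpadm_xmat <- function(bl, drop = NULL) {
  keep <- setdiff(seq_len(dim(bl$S)[1]), drop)
  S <- apply(bl$S[keep, , , drop = FALSE], c(2, 3), sum)
  C <- apply(bl$C[keep, , , drop = FALSE], c(2, 3), sum)
  S / C
}

# Constrained GLS: minimize (y - G'w)' Qinv (y - G'w) subject to sum(w) = 1.
qpadm_solve <- function(y, G, Qinv) {
  A <- G %*% Qinv %*% t(G)
  cvec <- G %*% Qinv %*% y
  Ainv <- solve(A)
  one <- rep(1, nrow(G))
  w0 <- Ainv %*% cvec
  lambda <- (1 - sum(w0)) / sum(Ainv %*% one)
  as.numeric(w0 + lambda * (Ainv %*% one))
}

safe_inverse <- function(Q, ridge = 1e-9, kappa_max = 1e12) {
  k <- tryCatch(kappa(Q, exact = TRUE), error = function(e) Inf)
  if (!is.finite(k) || k > kappa_max) {
    warning("near-singular f4 covariance; ridge-regularizing (epsilon = ",
            ridge, ")")
    Q <- Q + diag(ridge * mean(diag(Q)), nrow(Q))
  }
  solve(Q)
}

#' qpAdm admixture-proportion estimation
#'
#' Models a target population as a mixture of `sources` with weights
#' summing to 1, constrained by f4-statistics against a set of `rights`
#' (outgroup) reference populations. The weights solve a generalized
#' least-squares problem over the f4 vector
#' \eqn{f4(\cdot, r_1; r_j, r_1)}, with the residual covariance estimated
#' by weighted block jackknife (two GLS iterations from an ordinary
#' least-squares start). The model p-value is the tail probability of the
#' residual chi-square with `length(rights) - length(sources)` degrees of
#' freedom: small values reject the rank-deficiency (admixture) model. A
#' model is feasible when every weight lies in \[0, 1\].
#'
#' @param freqs a `pop_freq` from [allele_frequencies()].
#' @param target target population label.
#' @param sources ordered source ("left") population labels.
#' @param rights reference ("right") population labels; at least
#'   `length(sources) + 1`.
#' @param blocks a [make_blocks()] partition.
#' @return A `qpadm_result`: `weights`, `se`, `p_value`, `feasible`,
#'   `dof`, `chisq`, `n_snps_used`.
#' @export
qpadm_fit <- function(freqs, target, sources, rights, blocks) {
  if (length(rights) < length(sources) + 1)
    stop("need at least length(sources) + 1 right populations")
  if (target %in% c(sources, rights))
    stop("target must not appear among sources or rights")
  if (length(intersect(sources, rights)))
    stop("population(s) on both sides: ",
         paste(intersect(sources, rights), collapse = ", "))
  lefts <- c(target, sources)
  bl <- qpadm_blocks(freqs, lefts, rights, blocks)
  nb <- dim(bl$S)[1]
  nS <- length(sources)

  X <- qpadm_xmat(bl)
  y <- X[1, ]
  G <- X[-1, , drop = FALSE]

  # delete-one-block residual basis for the covariance
  loo_resid <- function(w) {
    t(vapply(seq_len(nb), function(b) {
      Xb <- qpadm_xmat(bl, drop = b)
      Xb[1, ] - as.numeric(t(w) %*% Xb[-1, , drop = FALSE])
    }, numeric(ncol(X))))
  }
  w <- qpadm_solve(y, G, diag(ncol(X)))          # OLS start
  for (it in 1:2) {
    r_full <- y - as.numeric(t(w) %*% G)
    Q <- weighted_jackknife_cov(r_full, loo_resid(w), bl$m)
    Qinv <- safe_inverse(Q)
    w <- qpadm_solve(y, G, Qinv)
  }
  r_full <- y - as.numeric(t(w) %*% G)
  Q <- weighted_jackknife_cov(r_full, loo_resid(w), bl$m)
  Qinv <- safe_inverse(Q)
  chisq <- as.numeric(t(r_full) %*% Qinv %*% r_full)
  dof <- length(rights) - length(sources)
  p <- pchisq(chisq, dof, lower.tail = FALSE)

  # block-jackknife SEs of the weights (Q held fixed from the full fit)
  loo_w <- t(vapply(seq_len(nb), function(b) {
    Xb <- qpadm_xmat(bl, drop = b)
    qpadm_solve(Xb[1, ], Xb[-1, , drop = FALSE], Qinv)
  }, numeric(nS)))
  se <- vapply(seq_len(nS), function(k)
    weighted_jackknife(w[k], loo_w[, k], bl$m)$se, 0)

  structure(list(target = target, sources = sources, rights = rights,
                 weights = stats::setNames(w, sources),
                 se = stats::setNames(se, sources),
                 p_value = p, chisq = chisq, dof = dof,
                 feasible = all(w >= 0 & w <= 1),
                 n_snps_used = min(apply(bl$C, c(2, 3), sum))),
            class = "qpadm_result")
}

#' @export
print.qpadm_result <- function(x, ...) {
  cat(sprintf("<qpadm> %s ~ %s | %d rights\n", x$target,
              paste(x$sources, collapse = " + "), length(x$rights)))
  for (i in seq_along(x$weights))
    cat(sprintf("  %-20s %7.3f +/- %.3f\n", names(x$weights)[i],
                x$weights[i], x$se[i]))
  cat(sprintf("  p = %.4g (chisq %.2f, dof %d)%s\n", x$p_value, x$chisq,
              x$dof, if (x$feasible) "" else "  [Not feasible]"))
  invisible(x)
}

#' Fit a grid of qpAdm models
#'
#' Runs [qpadm_fit()] for every (target, source-set) combination, the way
#' competing admixture models are screened for a cohort: each row reports
#' the weights, the rank-test p-value and the feasibility flag (all
#' weights in \[0, 1\]); rows with `p < 0.05` or infeasible weights are
#' marked. Per-cell failures are logged and reported as `NA` rows.
#'
#' @param freqs a `pop_freq`.
#' @param targets target population labels.
#' @param models a named list of character vectors, each a source set.
#' @param rights right (reference) population labels.
#' @param blocks a [make_blocks()] partition.
#' @return A `data.frame`, one row per (target, model): `target`, `model`,
#'   `sources`, `weights` (comma-joined), `p_value`, `feasible`,
#'   `rejected` (`p < 0.05`), with the `qpadm_result` objects in
#'   attribute `results`.
#' @export
qpadm_model_grid <- function(freqs, targets, models, rights, blocks) {
  if (!length(targets) || !length(models)) stop("empty model grid")
  if (is.null(names(models)))
    names(models) <- vapply(models, paste, "", collapse = "+")
  rows <- list(); fits <- list()
  for (tg in targets) for (mn in names(models)) {
    fit <- tryCatch(qpadm_fit(freqs, tg, models[[mn]], rights, blocks),
                    error = function(e) {
                      message("qpadm ", tg, " ~ ", mn, " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    key <- paste(tg, mn, sep = " ~ ")
    fits[[key]] <- fit
    rows[[key]] <- data.frame(
      target = tg, model = mn,
      sources = paste(models[[mn]], collapse = ","),
      weights = if (is.null(fit)) NA_character_
                else paste(sprintf("%.4f", fit$weights), collapse = ","),
      p_value = if (is.null(fit)) NA_real_ else fit$p_value,
      feasible = if (is.null(fit)) NA else fit$feasible,
      rejected = if (is.null(fit)) NA else fit$p_value < 0.05)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- fits
  out
}
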