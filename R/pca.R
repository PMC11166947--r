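#' PCA of modern reference genotypes
#'
#' smartpca-style analysis: SNPs with any missing modern call or without
#' polymorphism are dropped (logged); genotypes are centered by the SNP
#' mean and scaled by \eqn{\sqrt{p(1-p)}} with \eqn{p} half the mean; the
#' top `K` components come from the singular value decomposition of the
#' normalized matrix. Loading signs are fixed so the largest-magnitude
#' loading of each component is positive, making runs comparable.
#'
#' @param geno modern reference individuals, a diploid [geno_matrix()].
#' @param K number of components to retain.
#' @return A `pca_projection`: `loadings` (SNP x K, orthonormal),
#'   `coords` (modern individual coordinates, zero mean per component),
#'   `snp_mean`, `snp_scale`, `snp_used` (column indices), `var_explained`.
#' @export
pca_fit <- function(geno, K = 4) {
  v <- geno$values
  used <- which(colSums(is.na(v)) == 0)
  p <- colMeans(v[, used, drop = FALSE]) / 2
  poly <- p > 0 & p < 1
  if (any(!poly))
    message("dropping ", sum(!poly), " monomorphic SNP(s)")
  used <- used[poly]
  if (length(used) < ncol(v))
    message("PCA uses ", length(used), " of ", ncol(v), " SNPs")
  p <- p[poly]
  mu <- 2 * p
  sc <- sqrt(p * (1 - p))
  X <- sweep(sweep(v[, used, drop = FALSE], 2, mu), 2, sc, "/")
  if (K >= nrow(v)) stop("K must be smaller than the number of individuals")
  sv <- svd(X, nu = K, nv = K)
  flip <- vapply(seq_len(K), function(k) {
    l <- sv$v[, k]
    sign(l[which.max(abs(l))])
  }, 0)
  loadings <- sweep(sv$v, 2, flip, "*")
  coords <- sweep(sv$u %*% diag(sv$d[seq_len(K)], K), 2, flip, "*")
  rownames(coords) <- rownames(v)
  colnames(coords) <- paste0("PC", seq_len(K))
  structure(list(loadings = loadings, coords = coords, snp_mean = mu,
                 snp_scale = sc, snp_used = used,
                 var_explained = sv$d[seq_len(K)]^2 / sum(sv$d^2)),
            class = "pca_projection")
}

#' Project (ancient) individuals onto a fitted PCA
#'
#' Least-squares projection: each individual's normalized non-missing
#' calls are regressed on the loadings restricted to those SNPs, the
#' standard treatment of high-missingness pseudohaploid ancient genomes
#' (smartpca `lsqproject`). Individuals with fewer than `min_snps` usable
#' SNPs are flagged low-confidence; all-missing individuals get `NA`
#' coordinates.
#'
#' @param geno individuals to project, a [geno_matrix()] over the same
#'   SNP columns as the fit.
#' @param fit a `pca_projection` from [pca_fit()].
#' @param min_snps usable-SNP threshold below which the flag is raised.
#' @return A `data.frame`: individual, PC1..PCK, n_snps_used, flag
#'   (`"ok"`, `"low_confidence"` or `"no_data"`).
#' @export
project_onto_pca <- function(geno, fit, min_snps = 1000) {
  v <- geno$values[, fit$snp_used, drop = FALSE]
  K <- ncol(fit$loadings)
  n <- nrow(v)
  out <- matrix(NA_real_, n, K,
                dimnames = list(rownames(v), paste0("PC", seq_len(K))))
  nuse <- integer(n)
  flag <- character(n)
  for (i in seq_len(n)) {
    ok <- !is.na(v[i, ])
    nuse[i] <- sum(ok)
    if (nuse[i] == 0) {
      flag[i] <- "no_data"
      next
    }
    x <- (v[i, ok] - fit$snp_mean[ok]) / fit$snp_scale[ok]
    L <- fit$loadings[ok, , drop = FALSE]
    out[i, ] <- solve(crossprod(L), crossprod(L, x))
    flag[i] <- if (nuse[i] < min_snps) "low_confidence" else "ok"
  }
  data.frame(individual = rownames(v) %||% as.character(seq_len(n)),
             out, n_snps_used = nuse, flag = flag, row.names = NULL)
}
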