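# Shared machinery: per-SNP terms -> weighted block means -> Busing-style
# weighted delete-one-block jackknife. Each statistic uses every SNP at
# which all of its populations have an observed frequency (per-statistic
# masks, no global intersection).
fstat_jackknife <- function(kind, pops, terms, usable, blocks) {
  bidx <- block_index(blocks, length(usable))
  terms[!usable] <- 0
  bsum <- as.numeric(rowsum(terms, bidx, reorder = TRUE))
  bcnt <- as.numeric(rowsum(as.numeric(usable), bidx, reorder = TRUE))
  present <- which(bcnt > 0)
  if (length(present) < 2)
    stop(kind, "(", paste(pops, collapse = ", "),
         "): fewer than 2 usable jackknife blocks")
  bsum <- bsum[present]
  bcnt <- bcnt[present]
  est <- sum(bsum) / sum(bcnt)
  loo <- (sum(bsum) - bsum) / (sum(bcnt) - bcnt)
  jk <- weighted_jackknife(est, loo, bcnt)
  structure(list(kind = kind, pops = pops, estimate = est, se = jk$se,
                 z = est / jk$se, n_blocks = length(present),
                 n_snps_used = sum(bcnt)),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  Z %.2f  (%d SNPs, %d blocks)\n",
              x$kind, paste(x$pops, collapse = ", "), x$estimate, x$se,
              x$z, x$n_snps_used, x$n_blocks))
  invisible(x)
}

freq_row <- function(freqs, pop) {
  i <- match(pop, freqs$populations)
  if (is.na(i)) stop("population not in frequency table: ", pop)
  list(p = freqs$freq[i, ], n = freqs$obs[i, ])
}

#' Patterson f-statistics with block-jackknife standard errors
#'
#' `compute_f4(A, B, C, D)` averages \eqn{(p_A - p_B)(p_C - p_D)} per SNP;
#' `compute_f3(target; A, B)` averages \eqn{(p_T - p_A)(p_T - p_B)};
#' `compute_f2(A, B)` averages \eqn{(p_A - p_B)^2}. Estimates are
#' SNP-count-weighted block means with a weighted delete-one-block
#' jackknife standard error. With `correct_bias`, the target's (for f3) or
#' both populations' (for f2) finite-sample heterozygosity terms
#' \eqn{p(1-p)/(n-1)} are subtracted, with `n` the observed allele count;
#' outgroup-f3 ranking conventionally leaves the correction off.
#'
#' @param freqs a `pop_freq` from [allele_frequencies()].
#' @param A,B,C,D,target population labels.
#' @param blocks a [make_blocks()] partition of the SNP table the
#'   frequencies were computed on.
#' @param correct_bias subtract finite-sample heterozygosity terms.
#' @return An `fstat_result`: `estimate`, `se`, `z`, `n_blocks`,
#'   `n_snps_used`.
#' @export
compute_f4 <- function(freqs, A, B, C, D, blocks) {
  a <- freq_row(freqs, A); b <- freq_row(freqs, B)
  c_ <- freq_row(freqs, C); d <- freq_row(freqs, D)
  terms <- (a$p - b$p) * (c_$p - d$p)
  usable <- is.finite(a$p) & is.finite(b$p) & is.finite(c_$p) & is.finite(d$p)
  fstat_jackknife("f4", c(A, B, C, D), ifelse(usable, terms, 0), usable,
                  blocks)
}

#' @rdname compute_f4
#' @export
compute_f3 <- function(freqs, target, A, B, blocks, correct_bias = FALSE) {
  t_ <- freq_row(freqs, target)
  a <- freq_row(freqs, A); b <- freq_row(freqs, B)
  terms <- (t_$p - a$p) * (t_$p - b$p)
  usable <- is.finite(t_$p) & is.finite(a$p) & is.finite(b$p)
  if (correct_bias) {
    ok_n <- t_$n >= 2
    dropped <- usable & !ok_n
    if (any(dropped))
      message(sum(dropped), " SNP(s) dropped: target allele count < 2 ",
              "prevents the heterozygosity correction")
    usable <- usable & ok_n
    terms <- terms - t_$p * (1 - t_$p) / (t_$n - 1)
  }
  fstat_jackknife("f3", c(target, A, B), ifelse(usable, terms, 0), usable,
                  blocks)
}

#' @rdname compute_f4
#' @export
compute_f2 <- function(freqs, A, B, blocks, correct_bias = FALSE) {
  a <- freq_row(freqs, A); b <- freq_row(freqs, B)
  terms <- (a$p - b$p)^2
  usable <- is.finite(a$p) & is.finite(b$p)
  if (correct_bias) {
    ok_n <- a$n >= 2 & b$n >= 2
    usable <- usable & ok_n
    terms <- terms - a$p * (1 - a$p) / (a$n - 1) - b$p * (1 - b$p) / (b$n - 1)
  }
  fstat_jackknife("f2", c(A, B), ifelse(usable, terms, 0), usable, blocks)
}

#' Rank candidate populations by outgroup-f3 shared drift
#'
#' Computes `f3(outgroup; fixed, candidate)` for every candidate and
#' orders the results by descending estimate (shared drift with the fixed
#' population), ties broken by candidate name. Per-candidate failures are
#' logged and skipped.
#'
#' @param freqs a `pop_freq`.
#' @param outgroup the outgroup population (e.g. an African reference).
#' @param fixed the test population held fixed.
#' @param candidates candidate population labels (>= 1).
#' @param blocks a [make_blocks()] partition.
#' @return A `data.frame` (candidate, estimate, se, z, n_snps, n_blocks)
#'   in rank order, with the `fstat_result` objects as attribute
#'   `results`.
#' @export
rank_outgroup_f3 <- function(freqs, outgroup, fixed, candidates, blocks) {
  if (length(candidates) < 1) stop("need at least one candidate")
  res <- list()
  for (cand in candidates) {
    r <- tryCatch(compute_f3(freqs, outgroup, fixed, cand, blocks,
                             correct_bias = FALSE),
                  error = function(e) {
                    message("skipping candidate ", cand, ": ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(r)) res[[cand]] <- r
  }
  if (!length(res)) stop("no candidate produced a valid f3")
  df <- data.frame(candidate = names(res),
                   estimate = vapply(res, `[[`, 0, "estimate"),
                   se = vapply(res, `[[`, 0, "se"),
                   z = vapply(res, `[[`, 0, "z"),
                   n_snps = vapply(res, `[[`, 0, "n_snps_used"),
                   n_blocks = vapply(res, `[[`, 0, "n_blocks"),
                   row.names = NULL)
  ord <- order(-df$estimate, df$candidate)
  df <- df[ord, ]
  rownames(df) <- NULL
  attr(df, "results") <- res[ord]
  df
}

#' Write f-statistic results to a TSV report
#'
#' @param results a list of `fstat_result` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fstat_tsv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(kind = r$kind, pops = paste(r$pops, collapse = ","),
               estimate = r$estimate, se = r$se, z = r$z,
               n_snps = r$n_snps_used, n_blocks = r$n_blocks)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
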