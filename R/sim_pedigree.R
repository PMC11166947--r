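#' Degrade diploid genotypes to pseudohaploid calls
#'
#' Emulates low-coverage ancient-DNA genotyping: at each non-missing call
#' one allele is sampled uniformly and doubled (heterozygotes become 0 or
#' 2 with probability 1/2), then each call is set to missing independently
#' with probability `missing_rate`.
#'
#' @param geno a diploid [geno_matrix()].
#' @param missing_rate per-call missingness probability in \[0, 1\].
#' @param seed integer seed.
#' @return A pseudohaploid [geno_matrix()].
#' @export
degrade_to_pseudohaploid <- function(geno, missing_rate = 0, seed = 1) {
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  with_seed(seed, {
    v <- geno$values
    het <- which(!is.na(v) & v == 1L)
    v[het] <- 2L * rbinom(length(het), 1, 0.5)
    if (missing_rate > 0) {
      drop <- which(!is.na(v) & runif(length(v)) < missing_rate)
      v[drop] <- NA_integer_
    }
    out <- geno_matrix(v, "pseudohaploid")
    dimnames(out$values) <- dimnames(geno$values)
    out
  })
}

#' Simulate a pair of relatives by pedigree gene dropping
#'
#' Founders are drawn in Hardy-Weinberg proportions from a supplied allele
#' frequency spectrum at unlinked sites; descendants inherit one uniformly
#' chosen allele per site from each parent. The minimal pedigree realizing
#' each relationship is used: parent-offspring, full siblings, half
#' siblings (2nd degree), first cousins (3rd degree), or two independent
#' draws (unrelated).
#'
#' @param relationship one of `"parent-offspring"`, `"full-sib"`,
#'   `"half-sib"`, `"third-degree"`, `"unrelated"`.
#' @param founder_freqs alternative-allele frequency per SNP (length =
#'   number of SNPs), or a single count `n_snps` to draw frequencies
#'   uniformly on (0.05, 0.95).
#' @param seed integer seed.
#' @return A list: `geno` (diploid [geno_matrix()] of the two pair
#'   members, ids `pair1`/`pair2`), `ibd` (per SNP, number of alleles the
#'   pair shares identical by descent: 0, 1 or 2), `founder_freqs`.
#' @export
simulate_relative_pair <- function(relationship = c("parent-offspring",
                                                    "full-sib", "half-sib",
                                                    "third-degree",
                                                    "unrelated"),
                                   founder_freqs, seed = 1) {
  relationship <- match.arg(relationship)
  with_seed(seed, {
    if (length(founder_freqs) == 1 && founder_freqs > 1)
      founder_freqs <- runif(founder_freqs, 0.05, 0.95)
    p <- founder_freqs
    n <- length(p)
    if (n < 1) stop("need at least one SNP")
    next_id <- 0L
    founder <- function() {
      # two haplotypes: allele value 0/1 plus a globally unique ancestry tag
      next_id <<- next_id + 2L
      list(a = rbind(rbinom(n, 1, p), rbinom(n, 1, p)),
           tag = rbind(rep(next_id - 1L, n), rep(next_id, n)))
    }
    child <- function(mo, fa) {
      i <- rbinom(n, 1, 0.5) + 1
      j <- rbinom(n, 1, 0.5) + 1
      list(a = rbind(mo$a[cbind(i, seq_len(n))], fa$a[cbind(j, seq_len(n))]),
           tag = rbind(mo$tag[cbind(i, seq_len(n))],
                       fa$tag[cbind(j, seq_len(n))]))
    }
    pair <- switch(relationship,
      "parent-offspring" = {
        mo <- founder(); fa <- founder()
        list(mo, child(mo, fa))
      },
      "full-sib" = {
        mo <- founder(); fa <- founder()
        list(child(mo, fa), child(mo, fa))
      },
      "half-sib" = {
        shared <- founder()
        list(child(shared, founder()), child(shared, founder()))
      },
      "third-degree" = {
        gm <- founder(); gf <- founder()
        s1 <- child(gm, gf); s2 <- child(gm, gf)
        list(child(s1, founder()), child(s2, founder()))
      },
      "unrelated" = list(founder(), founder()))
    ibd <- integer(n)
    for (i in 1:2) for (j in 1:2)
      ibd <- ibd + (pair[[1]]$tag[i, ] == pair[[2]]$tag[j, ])
    ibd <- pmin(ibd, 2L)
    vals <- rbind(colSums(pair[[1]]$a), colSums(pair[[2]]$a))
    g <- geno_matrix(vals, "diploid")
    rownames(g$values) <- c("pair1", "pair2")
    list(geno = g, ibd = ibd, founder_freqs = p)
  })
}
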