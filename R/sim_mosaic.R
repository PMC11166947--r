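#' Simulate admixed chromosomes as ancestry mosaics
#'
#' Each chromosome copy of each admixed individual is a tiling of ancestry
#' segments: breakpoints fall as a Poisson process of rate `t_gens` per
#' Morgan (the recombination clock since a single pulse admixture) and each
#' segment draws its ancestry independently as source 1 with probability
#' `alpha`. The two source populations have allele frequencies diverged
#' from a common ancestral frequency by a Balding-Nichols beta
#' perturbation of scale `divergence`; genotypes are drawn per segment
#' from the segment source's frequency. This is exactly the generative
#' model the ancestry-covariance dating estimator inverts.
#'
#' @param alpha ancestry fraction from source 1, in (0, 1) (0 and 1 are
#'   allowed as degenerate single-source boundaries).
#' @param t_gens generations since admixture (> 0).
#' @param L_morgans chromosome length in Morgans (> 0).
#' @param n_ind number of admixed diploid individuals.
#' @param n_snps total SNP count, spread evenly over chromosomes.
#' @param n_chrom number of chromosomes.
#' @param divergence Balding-Nichols divergence scale between the sources
#'   (an Fst-like quantity).
#' @param seed integer seed.
#' @return A list: `mosaics` (per individual, per copy, per chromosome: a
#'   `data.frame` of segments with `start`, `end` in Morgans and
#'   `ancestry` 1 or 2, adjacent segments merged), `geno` (diploid
#'   [geno_matrix()]), `ind`, `snp` ([snp_table()], genetic positions in
#'   Morgans), `source_freqs` (`pop_freq` of the two true source
#'   frequencies), `ancestry_fraction` (realized genome-wide source-1
#'   fraction per individual), `breakpoint_counts` (raw crossover counts
#'   per individual, copy and chromosome, before same-ancestry merging).
#' @export
simulate_admixed_chromosomes <- function(alpha, t_gens, L_morgans = 1,
                                         n_ind = 50, n_snps = 10000,
                                         n_chrom = 20, divergence = 0.05,
                                         seed = 1) {
  if (L_morgans <= 0) stop("L_morgans must be positive")
  if (t_gens <= 0) stop("t_gens must be positive")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  with_seed(seed, {
    snp_per_chr <- diff(round(seq(0, n_snps, length.out = n_chrom + 1)))
    pos <- lapply(snp_per_chr, function(k) sort(runif(k, 0, L_morgans)))
    p_anc <- runif(n_snps, 0.05, 0.95)
    F <- divergence
    p_src <- rbind(rbeta(n_snps, p_anc * (1 - F) / F,
                         (1 - p_anc) * (1 - F) / F),
                   rbeta(n_snps, p_anc * (1 - F) / F,
                         (1 - p_anc) * (1 - F) / F))
    p_src <- pmin(pmax(p_src, 1e-4), 1 - 1e-4)
    rownames(p_src) <- c("src1", "src2")

    chr_of <- rep(seq_len(n_chrom), snp_per_chr)
    vals <- matrix(0L, n_ind, n_snps)
    mosaics <- vector("list", n_ind)
    anc_len <- numeric(n_ind)
    one_copy <- function() {
      k <- rpois(1, t_gens * L_morgans)
      bp <- sort(runif(k, 0, L_morgans))
      anc <- rbinom(k + 1, 1, alpha)      # 1 = source 1
      start <- c(0, bp)
      keep <- c(TRUE, anc[-1] != anc[-length(anc)])
      seg <- data.frame(start = start[keep],
                        end = c(start[keep][-1], L_morgans),
                        ancestry = 2L - anc[keep])
      list(seg = seg, k = k)
    }
    bp_counts <- vector("list", n_ind)
    for (i in seq_len(n_ind)) {
      copies <- list()
      kcount <- matrix(0L, 2, n_chrom)
      for (cp in 1:2) {
        per_chr <- vector("list", n_chrom)
        for (ch in seq_len(n_chrom)) {
          copy <- one_copy()
          seg <- copy$seg
          kcount[cp, ch] <- copy$k
          per_chr[[ch]] <- seg
          idx <- which(chr_of == ch)
          anc_of_snp <- seg$ancestry[findInterval(pos[[ch]], seg$start)]
          p <- p_src[cbind(anc_of_snp, idx)]
          vals[i, idx] <- vals[i, idx] + rbinom(length(idx), 1, p)
          anc_len[i] <- anc_len[i] +
            sum((seg$end - seg$start)[seg$ancestry == 1L])
        }
        copies[[cp]] <- per_chr
      }
      mosaics[[i]] <- copies
      bp_counts[[i]] <- kcount
    }
    anc_frac <- anc_len / (2 * n_chrom * L_morgans)

    gpos <- unlist(pos)
    ppos <- as.integer(round(gpos * 1e8)) + 1L
    for (ch in seq_len(n_chrom)) {     # enforce strict increase after rounding
      idx <- which(chr_of == ch)
      for (j in idx[-1]) ppos[j] <- max(ppos[j], ppos[j - 1] + 1L)
    }
    snp <- snp_table(paste0("m", seq_len(n_snps)), chr_of, gpos, ppos,
                     ref = "A", alt = "G")
    ind <- ind_table(sprintf("adm%03d", seq_len(n_ind)), "U", "admixed")
    g <- geno_matrix(vals, "diploid")
    rownames(g$values) <- ind$individual_id
    colnames(g$values) <- snp$snp_id
    list(mosaics = mosaics, geno = g, ind = ind, snp = snp,
         source_freqs = pop_freq_from_truth(p_src),
         ancestry_fraction = anc_frac, breakpoint_counts = bp_counts)
  })
}
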