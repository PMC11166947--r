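# Build the event schedule consumed by the C++ coalescent core: times in
# generations, populations as 0-based indices, events sorted by time with
# samples, then pulses (config order), then splits at tied times. Pulses are
# applied backward in time: a lineage currently in `dest` moves to `source`
# with probability alpha.
coalescent_schedule <- function(model, samples = NULL) {
  samples <- samples %||% model$samples
  if (!nrow(samples)) stop("model has no sample specification")
  g <- model$generation_time
  pops <- model$populations$name
  pid <- function(x) match(x, pops) - 1L

  n_axes <- nrow(samples)
  strides <- cumprod(c(1, head(samples$n_haploids + 1, -1)))
  ev <- rbind(
    data.frame(type = 0L, time = samples$time_ya / g,
               a = pid(samples$population), b = samples$n_haploids,
               frac = strides, ord = seq_len(nrow(samples))),
    if (nrow(model$pulses))
      data.frame(type = 1L, time = model$pulses$time_ya / g,
                 a = pid(model$pulses$dest), b = pid(model$pulses$source),
                 frac = model$pulses$alpha, ord = seq_len(nrow(model$pulses))),
    if (nrow(model$splits))
      data.frame(type = 2L, time = model$splits$time_ya / g,
                 a = pid(model$splits$child), b = pid(model$splits$parent),
                 frac = 0, ord = seq_len(nrow(model$splits))))
  ev <- ev[order(ev$time, ev$type, ev$ord), ]
  samp <- ev[ev$type == 0L, ]
  leaf_pop <- rep(samp$a + 1L, samp$b)              # population index per leaf
  leaf_axis <- rep(match(samp$frac, strides), samp$b) # sample axis per leaf
  list(n_pops = length(pops), ne = model$populations$ne,
       ev_type = ev$type, ev_time = ev$time, ev_a = ev$a, ev_b = ev$b,
       ev_frac = ev$frac,
       axis_pops = samples$population, axis_n = samples$n_haploids,
       strides = strides, n_cells = prod(samples$n_haploids + 1),
       leaf_pop_name = pops[leaf_pop],
       leaf_axis = leaf_axis)
}

sfs_from_cells <- function(cells, schedule) {
  # cells: 0-based flattened joint-SFS indices
  counts <- tabulate(cells + 1L, nbins = schedule$n_cells)
  a <- array(counts, dim = schedule$axis_n + 1)
  dimnames(a) <- lapply(seq_along(schedule$axis_n), function(j)
    as.character(0:schedule$axis_n[j]))
  names(dimnames(a)) <- schedule$axis_pops
  structure(a, class = "joint_sfs", type = "observed")
}

#' Simulate unlinked-site genotypes under a demographic model
#'
#' Draws one independent single-site genealogy per segregating site
#' (Hudson-style coalescent with dated sampling, backward pulse
#' reassignment and forced mergers at splits) and places one mutation per
#' site with probability proportional to branch length (infinite sites, a
#' known ancestral allele). Haploid genomes are paired in sample order into
#' diploid individuals. SNP metadata is synthetic: sites are spread evenly
#' over `n_chrom` chromosomes at 0.05 cM spacing, giving the block
#' jackknife a realistic substrate.
#'
#' @param model a [demography_model()].
#' @param n_sites number of segregating sites to draw.
#' @param seed integer seed (the simulator is seed-deterministic).
#' @param samples optional override of `model$samples`.
#' @param n_chrom chromosomes for the synthetic SNP map.
#' @return A list: `geno` ([geno_matrix()], diploid), `ind`
#'   ([ind_table()]), `snp` ([snp_table()]), `sfs` (observed joint SFS
#'   array, one axis per sampled population), `haps` (haploid 0/1 matrix,
#'   sites x haploids) and `cells` (per-site flattened SFS cell index,
#'   the site-level resampling unit for bootstraps).
#' @export
simulate_coalescent <- function(model, n_sites, seed, samples = NULL,
                                n_chrom = 22) {
  stopifnot(n_sites > 0)
  sch <- coalescent_schedule(model, samples)
  if (any(sch$axis_n %% 2 != 0))
    stop("n_haploids must be even per population to pair into diploids")
  if (sum(sch$axis_n) > 64)
    stop("at most 64 haploids in total (descendant sets are 64-bit masks)")
  res <- coal_sites_cpp(sch$n_pops, sch$ne, sch$ev_type, sch$ev_time,
                        sch$ev_a, sch$ev_b, sch$ev_frac,
                        length(sch$leaf_pop_name), as.integer(n_sites),
                        as.double(seed))
  haps <- res$haps
  n_hap <- ncol(haps)
  # pair consecutive haploids within each sample spec into diploids
  pair_first <- seq(1, n_hap - 1, by = 2)
  vals <- t(haps[, pair_first, drop = FALSE] +
            haps[, pair_first + 1, drop = FALSE])
  pops <- sch$leaf_pop_name[pair_first]
  ind <- ind_table(paste0(pops, "_", stats::ave(seq_along(pops), pops,
                                                FUN = seq_along)),
                   "U", pops)
  snp <- synthetic_snp_map(n_sites, n_chrom)
  g <- geno_matrix(vals, "diploid")
  rownames(g$values) <- ind$individual_id
  colnames(g$values) <- snp$snp_id
  list(geno = g, ind = ind, snp = snp,
       sfs = sfs_from_cells(res$cfg, sch), haps = haps, cells = res$cfg)
}

# Evenly spaced synthetic SNP map: `n_chrom` chromosomes, 0.05 cM and 50 kb
# between adjacent sites.
synthetic_snp_map <- function(n_sites, n_chrom = 22) {
  chrom <- sort(rep_len(seq_len(n_chrom), n_sites))
  within <- stats::ave(seq_len(n_sites), chrom, FUN = seq_along)
  snp_table(paste0("snp", seq_len(n_sites)), chrom,
            genetic_pos = within * 5e-4, physical_pos = within * 50000L,
            ref = "A", alt = "G")
}

#' Monte-Carlo expected joint site frequency spectrum
#'
#' Averages branch lengths subtending each derived-allele configuration
#' over `n_reps` independent genealogies, then normalizes over segregating
#' cells: the expected SFS conditional on a site segregating, under
#' infinite sites. Fixed (all-ancestral / all-derived) corner cells are
#' structurally zero and excluded.
#'
#' @inheritParams simulate_coalescent
#' @param n_reps genealogies to average (>= 1000 recommended).
#' @return A `joint_sfs` array of cell probabilities summing to 1.
#' @export
expected_sfs <- function(model, n_reps = 20000, seed = 1, samples = NULL) {
  stopifnot(n_reps >= 1)
  sch <- coalescent_schedule(model, samples)
  lens <- coal_expected_sfs_cpp(sch$n_pops, sch$ne, sch$ev_type, sch$ev_time,
                                sch$ev_a, sch$ev_b, sch$ev_frac,
                                sch$n_cells, as.integer(n_reps),
                                as.double(seed))
  a <- array(lens / sum(lens), dim = sch$axis_n + 1)
  dimnames(a) <- lapply(seq_along(sch$axis_n), function(j)
    as.character(0:sch$axis_n[j]))
  names(dimnames(a)) <- sch$axis_pops
  structure(a, class = "joint_sfs", type = "expected", n_reps = n_reps)
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("<joint_sfs> (%s) %s; populations: %s\n",
              attr(x, "type"), paste(dim(x), collapse = " x "),
              paste(names(dimnames(x)), collapse = ", ")))
  invisible(x)
}
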