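# Shared fixtures: small demographies built in code, in generation units
# (generation_time = 1) unless noted.

# Single constant-size population.
one_pop_model <- function(ne = 5000, n_haploids = 6) {
  demography_model(
    populations = data.frame(name = "A", ne = ne),
    samples = data.frame(population = "A", n_haploids = n_haploids,
                         time_ya = 0),
    generation_time = 1)
}

# Two populations split `t_split` generations ago.
two_pop_model <- function(t_split, ne = 5000, n_haploids = c(8, 8)) {
  demography_model(
    populations = data.frame(name = c("A", "B"), ne = ne),
    splits = data.frame(time_ya = t_split, child = "B", parent = "A"),
    samples = data.frame(population = c("A", "B"),
                         n_haploids = n_haploids, time_ya = 0),
    generation_time = 1)
}

# Four-taxon tree Out(((A,B),C)): A and B a recent clade, no admixture.
clade_model <- function(n_haploids = 8) {
  demography_model(
    populations = data.frame(name = c("Out", "C", "A", "B"),
                             ne = c(10000, 5000, 5000, 5000)),
    splits = data.frame(time_ya = c(3000, 1500, 400),
                        child = c("C", "A", "B"),
                        parent = c("Out", "C", "A")),
    samples = data.frame(population = c("Out", "C", "A", "B"),
                         n_haploids = n_haploids, time_ya = 0),
    generation_time = 1)
}

# qpAdm workbench: deep outgroups Out/RC, rights RA/RB that are recent
# sisters of the sources S1/S2, and a target T formed `alpha` from S2 and
# the rest from S1 by a pulse 60 generations ago.
qpadm_model <- function(alpha = 0.4, extra_pop = FALSE) {
  pops <- data.frame(
    name = c("Out", "RC", "RA", "RB", "S1", "S2", "T"),
    ne   = c(10000, 5000, 5000, 5000, 5000, 5000, 5000))
  splits <- data.frame(
    time_ya = c(2000, 1500, 1400, 400, 400, 100),
    child   = c("RC", "S1", "S2", "RA", "RB", "T"),
    parent  = c("Out", "RC", "S1", "S1", "S2", "S1"))
  pulses <- if (alpha > 0)
    data.frame(time_ya = 60, source = "S2", dest = "T", alpha = alpha)
  if (extra_pop) {  # deep lineage X, a source of ancestry absent from S1/S2
    pops <- rbind(pops, data.frame(name = "X", ne = 5000))
    splits <- rbind(splits,
                    data.frame(time_ya = 1800, child = "X", parent = "RC"))
    pulses <- data.frame(time_ya = 60, source = "X", dest = "T",
                         alpha = alpha)
  }
  demography_model(
    populations = pops, splits = splits, pulses = pulses,
    samples = data.frame(population = pops$name, n_haploids = 8,
                         time_ya = 0),
    generation_time = 1)
}

# Simulate genotypes and return the frequency/block bundle most tests need.
sim_bundle <- function(model, n_sites, seed) {
  sim <- simulate_coalescent(model, n_sites, seed)
  list(sim = sim,
       freqs = allele_frequencies(sim$geno, sim$ind),
       blocks = make_blocks(sim$snp))
}

# A 12-individual pseudohaploid cohort: 10 unrelated singletons plus one
# planted related pair, for degree-classification tests.
relative_cohort <- function(relationship, n_snps, seed,
                            missing_rate = 0.1) {
  p <- with_seed(seed, runif(n_snps, 0.05, 0.95))
  mats <- lapply(1:5, function(k)
    simulate_relative_pair("unrelated", p, seed = seed + 10 * k)$geno$values)
  rel <- simulate_relative_pair(relationship, p, seed = seed + 999)
  vals <- rbind(do.call(rbind, mats), rel$geno$values)
  rownames(vals) <- c(paste0("u", 1:10), "rel1", "rel2")
  degrade_to_pseudohaploid(geno_matrix(vals, "diploid"), missing_rate,
                           seed = seed + 1)
}

with_seed <- adnapop:::with_seed
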