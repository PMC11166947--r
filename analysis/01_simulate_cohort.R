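#!/usr/bin/env Rscript
# Stage 1 — synthetic study cohort.
#
# Simulates unlinked-site genotypes for the six populations of the packaged
# final demographic model (YRI, CHB, Loschbour, EEHG, Eastern Siberia LNBA,
# BOO), degrades the four ancient groups to pseudohaploid calls with 10%
# missingness (the aDNA regime), and writes the cohort as an EIGENSTRAT
# triplet plus the observed joint SFS. Later stages read these artifacts.

library(adnapop)
seed <- 20260929
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

model <- boo_final_model()
# larger samples than the SFS fit uses, so f-statistics are well resolved
samples <- data.frame(
  population = model$samples$population,
  n_haploids = c(16, 16, 8, 8, 8, 8),
  time_ya = model$samples$time_ya)

sim <- simulate_coalescent(model, n_sites = 60000, seed = seed,
                           samples = samples)
ancient <- sim$ind$population %in% c("Loschbour", "EEHG",
                                     "EasternSiberiaLNBA", "BOO")
vals <- sim$geno$values
deg <- degrade_to_pseudohaploid(
  geno_matrix(vals[ancient, , drop = FALSE], "diploid"),
  missing_rate = 0.10, seed = seed + 1)
vals[ancient, ] <- deg$values
geno <- geno_matrix(vals, ifelse(ancient, "pseudohaploid", "diploid"))
rownames(geno$values) <- sim$ind$individual_id

write_eigenstrat(geno, sim$snp, sim$ind, "results/cohort/boo_synthetic")
sfs_df <- as.data.frame.table(unclass(sim$sfs), responseName = "count")
write.table(sfs_df, "results/cohort/joint_sfs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "cohort: %d individuals x %d sites (%d pseudohaploid); %d SFS cells occupied\n",
  nrow(geno$values), ncol(geno$values), sum(ancient),
  sum(sim$sfs > 0)))
cat("wrote results/cohort/boo_synthetic.{geno,snp,ind} and joint_sfs.tsv\n")
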