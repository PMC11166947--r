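#!/usr/bin/env Rscript
# Stage 6 — projection PCA.
#
# Fits principal components on the modern reference populations of the
# synthetic cohort (YRI, CHB) plus a dense modern Eurasian panel simulated
# from the same model, then least-squares-projects the pseudohaploid
# ancient individuals onto that space. Admixed BOO should fall between
# its two source clusters, the synthetic analog of the published PCA
# placement.

library(adnapop)
seed <- 20260929
dir.create("results/pca", showWarnings = FALSE, recursive = TRUE)

model <- boo_final_model()
samples <- data.frame(
  population = c("YRI", "CHB", "Loschbour", "EEHG", "EasternSiberiaLNBA",
                 "BOO"),
  n_haploids = c(20, 20, 4, 4, 4, 6),
  time_ya = model$samples$time_ya)
sim <- simulate_coalescent(model, 30000, seed = seed, samples = samples)

modern_rows <- sim$ind$population %in% c("YRI", "CHB")
modern <- geno_matrix(sim$geno$values[modern_rows, ], "diploid")
ancient <- degrade_to_pseudohaploid(
  geno_matrix(sim$geno$values[!modern_rows, , drop = FALSE], "diploid"),
  missing_rate = 0.25, seed = seed + 1)

fit <- pca_fit(modern, K = 4)
proj <- project_onto_pca(ancient, fit)
proj$population <- sim$ind$population[!modern_rows]

coords <- data.frame(individual = rownames(modern$values),
                     population = sim$ind$population[modern_rows],
                     fit$coords, n_snps_used = length(fit$snp_used),
                     flag = "modern")
out <- rbind(coords,
             data.frame(individual = proj$individual,
                        population = proj$population,
                        proj[, paste0("PC", 1:4)],
                        n_snps_used = proj$n_snps_used, flag = proj$flag))
write.table(out, "results/pca/projection.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("variance explained by PC1-PC4: %s\n",
            paste(sprintf("%.1f%%", 100 * fit$var_explained), collapse = " ")))
cat("\nancient projections (PC1; modern cluster means in brackets):\n")
for (p in unique(proj$population))
  cat(sprintf("  %-20s PC1 = %s\n", p,
              paste(sprintf("%.1f", proj$PC1[proj$population == p]),
                    collapse = ", ")))
cat(sprintf("  [YRI] %.1f   [CHB] %.1f\n",
            mean(fit$coords[sim$ind$population[modern_rows] == "YRI", 1]),
            mean(fit$coords[sim$ind$population[modern_rows] == "CHB", 1])))
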