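#!/usr/bin/env Rscript
# Stage 5 — admixture-LD dating of the BOO pulse.
#
# Simulates BOO-like admixed chromosomes as ancestry mosaics at the
# model's configured admixture time, computes the weighted
# ancestry-covariance decay curve and fits the exponential to read off
# generations since admixture, then converts to calendar years.

library(adnapop)
seed <- 20260929
dir.create("results/dating", showWarnings = FALSE, recursive = TRUE)

model <- boo_final_model()
alpha <- get_parameter(model, "pulse.EasternSiberiaLNBA.BOO.alpha")
sample_age <- get_parameter(model, "sample.BOO.time")
t_true <- (get_parameter(model, "pulse.EasternSiberiaLNBA.BOO.time") -
           sample_age) / model$generation_time

sim <- simulate_admixed_chromosomes(alpha = alpha, t_gens = t_true,
                                    L_morgans = 1, n_ind = 100,
                                    n_snps = 50000, n_chrom = 20,
                                    divergence = 0.05, seed = seed)
curve <- ancestry_covariance(sim$geno, sim$source_freqs, sim$snp,
                             seed = seed + 1)
write.table(curve, "results/dating/decay_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fit <- fit_exponential(curve)
yrs <- generations_to_years(fit$t_gens, model$generation_time, sample_age)
jsonlite::write_json(
  list(t_gens = fit$t_gens, se = fit$se, amplitude = fit$amplitude,
       baseline = fit$baseline,
       years_before_sampling = yrs$years_before_sampling,
       years_ago = yrs$years_ago, truth_gens = t_true),
  "results/dating/date_fit.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("simulation truth: %.2f generations since admixture\n", t_true))
print(fit)
cat(sprintf("=> %.0f years before sampling; %.0f years ago at a %.0f-ya sample age\n",
            yrs$years_before_sampling, yrs$years_ago, sample_age))
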