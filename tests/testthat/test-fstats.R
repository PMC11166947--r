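# Frequencies stated directly (no sampling noise) for the exact-identity
# checks; three SNPs far apart so each is its own jackknife block.
hand_freqs <- function(freq_matrix) {
  adnapop:::pop_freq_from_truth(freq_matrix)
}
hand_blocks <- function(n) {
  make_blocks(snp_table(paste0("s", seq_len(n)), 1,
                        (seq_len(n) - 1) * 0.10, seq_len(n) * 100,
                        "A", "G"), span_cm = 5)
}

test_that("f4 identities hold exactly", {
  fm <- rbind(A = c(0.1, 0.5, 1.0), B = c(0.9, 0.3, 0.2),
              C = c(0.5, 0.1, 0.6), D = c(0.2, 0.8, 0.4))
  fr <- hand_freqs(fm)
  bl <- hand_blocks(3)
  expect_equal(compute_f4(fr, "A", "A", "C", "D", bl)$estimate, 0)
  f <- compute_f4(fr, "A", "B", "C", "D", bl)
  expect_equal(compute_f4(fr, "A", "B", "D", "C", bl)$estimate,
               -f$estimate, tolerance = 1e-12)
  expect_equal(compute_f4(fr, "B", "A", "C", "D", bl)$estimate,
               -f$estimate, tolerance = 1e-12)
  # |Z * SE - estimate| tiny by construction
  expect_lt(abs(f$z * f$se - f$estimate), 1e-12)
})

test_that("the three-SNP hand example gives estimate 1/3", {
  fm <- rbind(A = c(1, 0.5, 1), B = c(0, 0.5, 0),
              C = c(1, 1, 0.5), D = c(0, 0, 0.5))
  f <- compute_f4(hand_freqs(fm), "A", "B", "C", "D", hand_blocks(3))
  # per-SNP terms (1, 0, 0), equal weights
  expect_equal(f$estimate, 1 / 3, tolerance = 1e-12)
  expect_equal(f$n_snps_used, 3)
  expect_equal(f$n_blocks, 3)
})

test_that("f4 is additive over the fourth slot on identical SNP sets", {
  b <- sim_bundle(clade_model(), 3000, seed = 13)
  f_cd <- compute_f4(b$freqs, "A", "B", "C", "Out", b$blocks)
  f_ce <- compute_f4(b$freqs, "A", "B", "C", "B", b$blocks)
  f_ed <- compute_f4(b$freqs, "A", "B", "B", "Out", b$blocks)
  expect_equal(f_cd$estimate, f_ce$estimate + f_ed$estimate,
               tolerance = 1e-12)
})

test_that("f3 is symmetric and reduces to f2 for duplicated arguments", {
  b <- sim_bundle(clade_model(), 3000, seed = 14)
  expect_equal(compute_f3(b$freqs, "Out", "A", "B", b$blocks)$estimate,
               compute_f3(b$freqs, "Out", "B", "A", b$blocks)$estimate,
               tolerance = 1e-12)
  expect_equal(compute_f3(b$freqs, "Out", "A", "A", b$blocks)$estimate,
               compute_f2(b$freqs, "Out", "A", b$blocks)$estimate,
               tolerance = 1e-12)
  expect_gte(compute_f2(b$freqs, "A", "B", b$blocks)$estimate, 0)
})

test_that("bias-corrected f3 detects a fresh 50/50 admixture", {
  m <- demography_model(
    populations = data.frame(name = c("O", "S1", "S2", "T"),
                             ne = c(10000, 5000, 5000, 5000)),
    splits = data.frame(time_ya = c(3000, 1500, 10),
                        child = c("S1", "S2", "T"),
                        parent = c("O", "S1", "S1")),
    pulses = data.frame(time_ya = 5, source = "S2", dest = "T",
                        alpha = 0.5),
    samples = data.frame(population = c("O", "S1", "S2", "T"),
                         n_haploids = c(8, 8, 8, 12), time_ya = 0),
    generation_time = 1)
  b <- sim_bundle(m, 50000, seed = 15)
  f3 <- compute_f3(b$freqs, "T", "S1", "S2", b$blocks, correct_bias = TRUE)
  expect_lt(f3$estimate, 0)
  expect_lt(f3$z, -3)
})

test_that("outgroup-f3 ranking puts the sister population first", {
  b <- sim_bundle(clade_model(), 5000, seed = 16)
  rk <- rank_outgroup_f3(b$freqs, "Out", "A", c("C", "B"), b$blocks)
  expect_equal(rk$candidate[1], "B")   # B is the sister of A; C is distant
  rk1 <- rank_outgroup_f3(b$freqs, "Out", "A", "B", b$blocks)
  expect_equal(nrow(rk1), 1)
})

test_that("tied candidates rank in name order with identical estimates", {
  fm <- rbind(O = c(0.2, 0.5, 0.9), A = c(0.4, 0.1, 0.3),
              Zcopy = c(0.3, 0.6, 0.5), Bcopy = c(0.3, 0.6, 0.5))
  rk <- rank_outgroup_f3(hand_freqs(fm), "O", "A", c("Zcopy", "Bcopy"),
                         hand_blocks(3))
  expect_equal(rk$estimate[1], rk$estimate[2])
  expect_equal(rk$candidate, c("Bcopy", "Zcopy"))
})

test_that("per-statistic masks drop SNPs undefined in any used population", {
  fm <- rbind(A = c(0.1, 0.5, 1.0), B = c(0.9, NaN, 0.2),
              C = c(0.5, 0.1, 0.6), D = c(0.2, 0.8, 0.4))
  fr <- hand_freqs(fm)
  f <- compute_f4(fr, "A", "B", "C", "D", hand_blocks(3))
  expect_equal(f$n_snps_used, 2)
  expect_error(compute_f4(fr, "A", "E", "C", "D", hand_blocks(3)),
               "not in frequency table")
})

test_that("f4 on a true clade is null-calibrated across replicates", {
  m <- clade_model()
  zs <- vapply(1:40, function(s) {
    b <- sim_bundle(m, 2500, seed = 400 + s)
    compute_f4(b$freqs, "Out", "C", "A", "B", b$blocks)$z
  }, 0)
  # (A,B) form a clade: f4(Out, C; A, B) should be consistent with zero
  expect_gte(mean(abs(zs) < 3), 0.9)
})
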