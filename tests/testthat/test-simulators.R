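test_that("simulators are seed-deterministic", {
  m <- one_pop_model()
  a <- simulate_coalescent(m, 500, seed = 9)
  b <- simulate_coalescent(m, 500, seed = 9)
  c <- simulate_coalescent(m, 500, seed = 10)
  expect_identical(a$haps, b$haps)
  expect_false(identical(a$haps, c$haps))
  expect_identical(expected_sfs(m, 2000, seed = 4),
                   expected_sfs(m, 2000, seed = 4))
  s1 <- simulate_admixed_chromosomes(0.3, 10, n_ind = 5, n_snps = 1000,
                                     seed = 2)
  s2 <- simulate_admixed_chromosomes(0.3, 10, n_ind = 5, n_snps = 1000,
                                     seed = 2)
  expect_identical(s1$geno$values, s2$geno$values)
})

test_that("single-population SFS matches the Watterson 1/i shape", {
  e <- expected_sfs(one_pop_model(n_haploids = 6), n_reps = 40000, seed = 1)
  shape <- as.numeric(e)[2:6]
  expect_equal(shape / shape[1], 1 / (1:5), tolerance = 0.05)
})

test_that("mean pairwise diversity per segregating site matches enumeration", {
  # oracle: with P(i) proportional to 1/i, expected pairwise difference per
  # segregating site is sum_i P(i) 2 i (n - i) / (n (n - 1))
  n <- 6
  p_i <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  oracle <- sum(p_i * 2 * (1:(n - 1)) * (n - (1:(n - 1))) / (n * (n - 1)))
  sim <- simulate_coalescent(one_pop_model(n_haploids = 6), 20000, seed = 3)
  dac <- rowSums(sim$haps)
  pi_hat <- mean(2 * dac * (n - dac) / (n * (n - 1)))
  expect_equal(pi_hat, oracle, tolerance = 0.03)
})

test_that("zero post-split drift gives f2 near zero", {
  m <- two_pop_model(t_split = 1, ne = 1e7)
  b <- sim_bundle(m, 5000, seed = 5)
  f2 <- compute_f2(b$freqs, "A", "B", b$blocks, correct_bias = TRUE)
  expect_lt(abs(f2$z), 3)
})

test_that("joint simulator marginals match an independent single-pop oracle", {
  # plain-R coalescent for one population: expected branch length with i
  # descendants among n, accumulated over trees
  r_oracle_sfs <- function(n, ne, reps, seed) {
    lens <- numeric(n - 1)
    with_seed(seed, {
      for (r in seq_len(reps)) {
        k <- n
        sizes <- as.list(rep(1, n))
        t <- 0
        while (k > 1) {
          dt <- rexp(1, k * (k - 1) / 2 / (2 * ne))
          pick <- sample(k, 2)
          # each surviving lineage accrues length; accumulate per interval
          for (sz in unlist(sizes)) if (sz < n)
            lens[sz] <- lens[sz] + dt
          sizes[[pick[1]]] <- sizes[[pick[1]]] + sizes[[pick[2]]]
          sizes[[pick[2]]] <- NULL
          k <- k - 1
        }
      }
    })
    lens / sum(lens)
  }
  oracle <- r_oracle_sfs(4, 5000, 3000, seed = 8)
  e <- expected_sfs(one_pop_model(n_haploids = 4), n_reps = 20000, seed = 2)
  expect_equal(as.numeric(e)[2:4], oracle, tolerance = 0.05)
})

test_that("mosaic breakpoints follow the Poisson recombination clock", {
  sim <- simulate_admixed_chromosomes(0.5, 18, L_morgans = 1, n_ind = 100,
                                      n_snps = 2000, n_chrom = 2, seed = 6)
  counts <- unlist(sim$breakpoint_counts)
  expect_equal(mean(counts), 18, tolerance = 3 * sqrt(18 / length(counts)) / 18 + 0.02)
  # merged ancestry-1 interior segments: exponential shape with mean near
  # 1/(t (1 - alpha)) (switches out of ancestry 1 thin the breakpoints);
  # finite chromosomes shorten interior segments slightly, so the density
  # is pushed up (t = 60) and the mean tolerance left at 10%
  sim2 <- simulate_admixed_chromosomes(0.5, 60, L_morgans = 1, n_ind = 100,
                                       n_snps = 400, n_chrom = 2, seed = 6)
  segs <- unlist(lapply(sim2$mosaics, function(ind) lapply(ind, function(cp)
    lapply(cp, function(seg) {
      n <- nrow(seg)
      if (n < 3) return(numeric(0))
      mid <- seg[-c(1, n), ]
      mid$end[mid$ancestry == 1] - mid$start[mid$ancestry == 1]
    }))))
  expect_equal(mean(segs), 1 / (60 * 0.5), tolerance = 0.1)
  ks <- suppressWarnings(stats::ks.test(segs, "pexp", 1 / mean(segs)))
  expect_gt(ks$p.value, 0.01)
})

test_that("mosaic ancestry fractions and boundaries behave", {
  s0 <- simulate_admixed_chromosomes(0, 10, n_ind = 4, n_snps = 500,
                                     n_chrom = 2, seed = 3)
  expect_equal(s0$ancestry_fraction, rep(0, 4))
  expect_true(all(unlist(lapply(s0$mosaics, function(i)
    lapply(i, function(cp) lapply(cp, function(seg) seg$ancestry)))) == 2))
  s <- simulate_admixed_chromosomes(0.3, 15, n_ind = 200, n_snps = 200,
                                    n_chrom = 4, seed = 4)
  se <- stats::sd(s$ancestry_fraction) / sqrt(200)
  expect_lt(abs(mean(s$ancestry_fraction) - 0.3), 3 * se)
  # adjacent segments always alternate ancestry
  ok <- unlist(lapply(s$mosaics, function(i) lapply(i, function(cp)
    lapply(cp, function(seg) all(diff(seg$ancestry) != 0)))))
  expect_true(all(ok))
  expect_error(simulate_admixed_chromosomes(0.3, 15, L_morgans = -1), "positive")
})

test_that("pseudohaploid degradation follows the sampled-allele model", {
  v <- matrix(c(rep(0L, 50), rep(1L, 2000), rep(2L, 50)), nrow = 1)
  g <- geno_matrix(v, "diploid")
  d0 <- degrade_to_pseudohaploid(g, 0, seed = 2)
  expect_true(all(d0$values[1, 1:50] == 0))
  expect_true(all(d0$values[1, 2051:2100] == 2))
  hets <- d0$values[1, 51:2050]
  expect_true(all(hets %in% c(0L, 2L)))
  expect_equal(mean(hets == 2), 0.5, tolerance = 3 * 0.5 / sqrt(2000))
  d1 <- degrade_to_pseudohaploid(g, 1, seed = 2)
  expect_true(all(is.na(d1$values)))
  expect_error(degrade_to_pseudohaploid(g, 1.5), "\\[0, 1\\]")
})

test_that("pedigree gene dropping realizes the expected IBD sharing", {
  p <- with_seed(1, runif(5000, 0.05, 0.95))
  po <- simulate_relative_pair("parent-offspring", p, seed = 3)
  expect_true(all(po$ibd >= 1))
  # parent and child always share an allele at every site
  share <- abs(po$geno$values[1, ] - po$geno$values[2, ]) < 2
  expect_true(all(share))
  ibd_mean <- function(rel, seeds) mean(vapply(seeds, function(s)
    mean(simulate_relative_pair(rel, p, seed = s)$ibd) / 2, 0))
  expect_equal(ibd_mean("half-sib", 1:30), 0.25, tolerance = 0.02)
  expect_equal(ibd_mean("third-degree", 1:30), 0.125, tolerance = 0.02)
  expect_equal(ibd_mean("unrelated", 1:10), 0)
})

test_that("unrelated-pair pseudohaploid mismatch matches HW enumeration", {
  p <- with_seed(2, runif(30000, 0.05, 0.95))
  # enumeration oracle: two independent allele draws differ with
  # probability 2 p (1 - p)
  oracle <- mean(2 * p * (1 - p))
  un <- simulate_relative_pair("unrelated", p, seed = 5)
  g <- degrade_to_pseudohaploid(un$geno, 0, seed = 6)
  r <- pmr(g, "pair1", "pair2", min_overlap = 100)
  expect_equal(r$mismatch_rate, oracle, tolerance = 0.02)
})
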