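test_that("expected SFS for one population follows the 1/i law", {
  e <- expected_sfs(one_pop_model(n_haploids = 4), n_reps = 30000, seed = 2)
  vals <- as.numeric(e)[2:4]
  expect_equal(vals / sum(vals), (1 / (1:3)) / sum(1 / (1:3)),
               tolerance = 0.02)
})

test_that("a complete pulse just before sampling relabels the source", {
  m <- demography_model(
    populations = data.frame(name = c("A", "B"), ne = 4000),
    splits = data.frame(time_ya = 2000, child = "B", parent = "A"),
    pulses = data.frame(time_ya = 1, source = "A", dest = "B", alpha = 1),
    samples = data.frame(population = c("A", "B"), n_haploids = 4,
                         time_ya = 0),
    generation_time = 1)
  e <- expected_sfs(m, n_reps = 30000, seed = 3)
  # with all B lineages instantly moved into A, the joint SFS must look
  # like two samples of A itself
  m_ref <- demography_model(
    populations = data.frame(name = c("A", "B"), ne = 4000),
    splits = data.frame(time_ya = 1, child = "B", parent = "A"),
    samples = data.frame(population = c("A", "B"), n_haploids = 4,
                         time_ya = 0),
    generation_time = 1)
  e_ref <- expected_sfs(m_ref, n_reps = 30000, seed = 4)
  expect_equal(as.numeric(e), as.numeric(e_ref), tolerance = 0.02)
})

test_that("composite log-likelihood satisfies the entropy identity", {
  e <- expected_sfs(two_pop_model(800, n_haploids = c(4, 4)),
                    n_reps = 5000, seed = 5)
  n_tot <- 10000
  obs <- unclass(e) * n_tot
  attr(obs, "type") <- "observed"
  class(obs) <- "joint_sfs"
  ll <- composite_loglik(obs, e)
  # direct summation oracle over non-corner cells
  p <- as.numeric(e)
  keep <- !adnapop:::corner_mask(e) & p > 0
  expect_equal(ll, n_tot * sum(p[keep] * log(p[keep])), tolerance = 1e-8)
  # single-cell observation
  obs1 <- obs; obs1[] <- 0
  k <- which(p > 0)[5]
  obs1[k] <- 7
  expect_equal(composite_loglik(obs1, e), 7 * log(p[k]))
  expect_error(composite_loglik(obs1, expected_sfs(one_pop_model(),
                                                   100, 1)), "dimensions")
})

test_that("consistent axis permutation leaves the likelihood unchanged", {
  e <- expected_sfs(two_pop_model(800, n_haploids = c(4, 6)),
                    n_reps = 5000, seed = 6)
  sim <- simulate_coalescent(two_pop_model(800, n_haploids = c(4, 6)),
                             3000, seed = 7)
  obs <- sim$sfs
  perm <- function(a) {
    out <- aperm(unclass(a), c(2, 1))
    class(out) <- "joint_sfs"
    out
  }
  expect_equal(composite_loglik(perm(obs), perm(e)),
               composite_loglik(obs, e))
})

test_that("profiling observed-equals-expected data peaks at the truth", {
  m <- qpadm_model(alpha = 0.4)
  grid <- seq(0.2, 0.6, by = 0.05)
  truth_idx <- match(0.4, grid)
  e_truth <- expected_sfs(m, n_reps = 30000, seed = 8)
  obs <- unclass(e_truth) * 50000
  class(obs) <- "joint_sfs"
  # off-truth grid points have zero expectation in cells the truth
  # populates, so flooring warnings are expected here
  fit <- suppressWarnings(
    fit_parameter_profile(m, "pulse.S2.T.alpha", grid, obs,
                          n_reps = 30000, seed = 8))
  expect_equal(fit$estimate_grid, grid[truth_idx])
})

test_that("a pulse fraction is recovered with a covering bootstrap CI", {
  m <- qpadm_model(alpha = 0.4)
  sim <- simulate_coalescent(m, 30000, seed = 9)
  fit <- bootstrap_ci(m, "pulse.S2.T.alpha", seq(0.2, 0.6, by = 0.05),
                      sim$cells, n_reps = 50000, n_boot = 40, seed = 10)
  expect_lt(abs(fit$estimate - 0.4), 0.05)
  expect_lte(fit$ci[1], fit$estimate)
  expect_gte(fit$ci[2], fit$estimate)
  expect_true(fit$ci[1] <= 0.4 && fit$ci[2] >= 0.4)
})

test_that("bootstrap machinery is well-formed at tiny n_boot", {
  m <- two_pop_model(800, n_haploids = c(4, 4))
  sim <- simulate_coalescent(m, 2000, seed = 11)
  fit <- bootstrap_ci(m, "split.B", seq(400, 1200, by = 100), sim$cells,
                      n_reps = 10000, n_boot = 2, seed = 12)
  expect_length(fit$ci, 2)
  expect_lte(fit$ci[1], fit$ci[2])
  expect_equal(fit$n_boot, 2)
})

test_that("parameters without observable effect are flagged unidentifiable", {
  m <- demography_model(
    populations = data.frame(name = c("A", "B", "Ghost"),
                             ne = c(5000, 5000, 5000)),
    splits = data.frame(time_ya = c(800, 600), child = c("B", "Ghost"),
                        parent = c("A", "A")),
    samples = data.frame(population = c("A", "B"), n_haploids = 4,
                         time_ya = 0),
    generation_time = 1)
  sim <- simulate_coalescent(m, 2000, seed = 13)
  expect_warning(
    fit <- fit_parameter_profile(m, "ne.Ghost",
                                 c(1000, 2000, 4000, 8000, 16000),
                                 sim$sfs, n_reps = 5000, seed = 14),
    "unidentifiable")
  expect_true(fit$unidentifiable)
})

test_that("bootstrap CI width shrinks roughly as one over root n", {
  m <- two_pop_model(600, n_haploids = c(6, 6))
  grid <- seq(300, 1000, by = 70)
  width <- function(n_sites, seed) {
    sim <- simulate_coalescent(m, n_sites, seed = seed)
    f <- bootstrap_ci(m, "split.B", grid, sim$cells, n_reps = 60000,
                      n_boot = 60, seed = 15)
    f$ci[2] - f$ci[1]
  }
  w1 <- width(4000, 16)
  w4 <- width(16000, 17)
  ratio <- w1 / w4   # expect about 2 for a fourfold site increase
  expect_gt(ratio, 2 / 1.5)
  expect_lt(ratio, 2 * 1.5)
})
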