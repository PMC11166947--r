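test_that("EIGENSTRAT triplets round-trip through write and read", {
  vals <- matrix(c(0L, 1L, 2L, NA, 2L, 0L), nrow = 2)
  g <- geno_matrix(vals, "diploid")
  snp <- snp_table(c("s1", "s2", "s3"), c(1, 1, 2), c(0, 0.01, 0),
                   c(100, 200, 100), c("A", "A", "C"), c("G", "T", "T"))
  ind <- ind_table(c("i1", "i2"), c("M", "F"), c("pop1", "pop2"))
  prefix <- file.path(tempdir(), "toy")
  write_eigenstrat(g, snp, ind, prefix)
  back <- suppressMessages(read_eigenstrat(prefix))
  expect_equal(unname(back$geno$values), vals)
  expect_equal(back$snp$snp_id, snp$snp_id)
  expect_equal(back$snp$genetic_pos, snp$genetic_pos)
  expect_equal(back$ind$population, ind$population)
})

test_that("geno rows parse digit-wise with 9 as missing", {
  prefix <- file.path(tempdir(), "digits")
  writeLines("092", paste0(prefix, ".geno"))
  writeLines("s1\t1\t0.0\t100\tA\tG", paste0(prefix, ".snp"))
  writeLines(c("a\tU\tp", "b\tU\tp", "c\tU\tp"), paste0(prefix, ".ind"))
  got <- suppressMessages(read_eigenstrat(prefix))
  expect_equal(unname(got$geno$values[, 1]), c(0L, NA, 2L))
})

test_that("dimension mismatches and bad characters are structured errors", {
  prefix <- file.path(tempdir(), "bad")
  writeLines(c("00", "11", "22", "00"), paste0(prefix, ".geno"))
  writeLines(sprintf("s%d\t1\t0.0%d\t%d\tA\tG", 1:5, 1:5, 1:5 * 100),
             paste0(prefix, ".snp"))
  writeLines(c("a\tU\tp", "b\tU\tp"), paste0(prefix, ".ind"))
  expect_error(read_eigenstrat(prefix), "dimension mismatch.*4 rows.*5")
  writeLines(c("0x"), paste0(prefix, ".geno"))
  writeLines("s1\t1\t0.0\t100\tA\tG", paste0(prefix, ".snp"))
  expect_error(suppressMessages(read_eigenstrat(prefix)), "non-digit")
})

test_that("geno_matrix enforces the pseudohaploid no-heterozygote rule", {
  expect_error(geno_matrix(matrix(1L, 1, 3), "pseudohaploid"),
               "heterozygous")
  expect_silent(geno_matrix(matrix(c(0L, 2L, NA), 1), "pseudohaploid"))
})

test_that("allele frequencies follow diploid and pseudohaploid counting", {
  # lone diploid het: frequency 1/2 over two observed alleles
  g <- geno_matrix(matrix(1L, 1, 1), "diploid")
  ind <- ind_table("a", "U", "p")
  fr <- allele_frequencies(g, ind)
  expect_equal(unname(fr$freq[1, 1]), 0.5)
  expect_equal(unname(fr$obs[1, 1]), 2)
  # pseudohaploid {0, 2, NA}: two observed calls, four allele copies
  g2 <- geno_matrix(matrix(c(0L, 2L, NA), 3, 1), "pseudohaploid")
  ind2 <- ind_table(c("a", "b", "c"), "U", "p")
  fr2 <- allele_frequencies(g2, ind2)
  expect_equal(unname(fr2$alt[1, 1]), 2)
  expect_equal(unname(fr2$obs[1, 1]), 4)
  expect_equal(unname(fr2$freq[1, 1]), 0.5)
  expect_error(allele_frequencies(g, ind, populations = "ghost"), "ghost")
})

test_that("frequencies match a brute-force tally on a random matrix", {
  vals <- with_seed(11, matrix(sample(c(0:2, NA), 20 * 50, replace = TRUE),
                               20, 50))
  pops <- rep(c("p1", "p2"), each = 10)
  g <- geno_matrix(vals, "diploid")
  ind <- ind_table(paste0("i", 1:20), "U", pops)
  fr <- allele_frequencies(g, ind)
  # independent tally: explicit double loop
  for (p in c("p1", "p2")) {
    rows <- which(pops == p)
    for (j in c(1, 17, 50)) {
      alt <- obs <- 0
      for (i in rows) {
        if (!is.na(vals[i, j])) {
          alt <- alt + vals[i, j]
          obs <- obs + 2
        }
      }
      expect_equal(unname(fr$alt[p, j]), alt)
      expect_equal(unname(fr$obs[p, j]), obs)
    }
  }
  # invariance under permutation of individuals within populations
  perm <- c(sample(1:10), sample(11:20))
  fr_p <- allele_frequencies(geno_matrix(vals[perm, ], "diploid"),
                             ind_table(paste0("i", 1:20), "U", pops[perm]))
  expect_equal(fr_p$freq, fr$freq)
})

test_that("block partition follows the greedy span rule and tiles all SNPs", {
  # 10 SNPs spanning 4 cM: a single block
  s1 <- snp_table(paste0("s", 1:10), 1, seq(0, 0.04, length.out = 10),
                  1:10 * 100, "A", "G")
  b1 <- make_blocks(s1, span_cm = 5)
  expect_equal(nrow(b1), 1)
  # uniform 0.1 cM spacing, 1000 SNPs, 5 cM span: 20 blocks of 50
  s2 <- snp_table(paste0("s", 1:1000), 1, (0:999) * 0.001,  # 0.1 cM steps
                  1:1000 * 100, "A", "G")
  b2 <- make_blocks(s2, span_cm = 5)
  expect_equal(nrow(b2), 20)
  expect_true(all(b2$end - b2$start == 50))
  # blocks never span chromosomes and tile everything exactly once
  s3 <- snp_table(paste0("s", 1:40), rep(1:2, each = 20),
                  rep(seq(0, 0.019, length.out = 20), 2),
                  rep(1:20 * 100, 2), "A", "G")
  b3 <- make_blocks(s3, span_cm = 1)
  idx <- adnapop:::block_index(b3, 40)
  expect_equal(sum(b3$end - b3$start), 40)
  for (b in seq_len(nrow(b3)))
    expect_length(unique(s3$chromosome[idx == b]), 1)
  expect_error(make_blocks(s1, span_cm = 0), "positive")
})
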