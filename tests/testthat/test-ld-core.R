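test_that("EM recovers phase-known haplotype counts exactly", {
  wt <- worked_example_tables()
  f <- em_haplotype_freqs(wt$phase_known)   # 2 x AABB, 2 x aabb
  expect_equal(f$pAB, 0.5)
  expect_equal(f$pab, 0.5)
  expect_equal(f$pAb, 0)
  expect_equal(f$paB, 0)
  # general phase-known fixture: no double heterozygotes -> direct counting
  cnt <- tab3(n22 = 3, n21 = 2, n12 = 1, n00 = 4, n01 = 2)
  f <- em_haplotype_freqs(cnt)
  n2 <- 2 * sum(cnt)
  expect_equal(f$pAB, (2 * 3 + 2 + 1) / n2)
  expect_equal(f$pAb, (2 * 0 + 2 + 0) / n2)
  expect_equal(f$paB, (0 + 2 + 1) / n2)
  expect_equal(f$pab, (2 * 4 + 2 + 0) / n2)
})

test_that("double-heterozygote-only table stays at the equilibrium
           stationary point and is flagged", {
  f <- em_haplotype_freqs(worked_example_tables()$double_het_only)
  expect_equal(f$pAB, 0.25)
  expect_true(f$saddle)
  ld <- ld_from_freqs(f)
  expect_equal(ld$D, 0)
  expect_equal(ld$Dprime, 0)
})

test_that("EM matches the fine-grid likelihood oracle on the mixed table", {
  cnt <- worked_example_tables()$em_mixed
  f <- em_haplotype_freqs(cnt)
  oracle <- oracle_grid_max(cnt, step = 1e-6)
  expect_equal(f$pAB, oracle$pAB, tolerance = 1e-4)
  expect_gte(oracle_loglik(cnt, f$pAB), oracle$loglik - 1e-6)
})

test_that("preconditions: tiny or monomorphic tables are rejected", {
  expect_error(em_haplotype_freqs(tab3(n22 = 1)), "at least 2")
  expect_error(em_haplotype_freqs(tab3(n22 = 2, n20 = 2)),
               "monomorphic")   # marker 1 fixed at dosage 2
})

test_that("LD statistics match hand evaluation", {
  e <- ld_from_freqs(list(pA = 0.6, pB = 0.5, pAB = 0.35))
  expect_equal(e$D, 0.05)
  expect_equal(e$Dmax, 0.20)
  expect_equal(e$Dprime, 0.25)
  expect_equal(e$r2, 0.0025 / 0.06)
  # equilibrium
  e <- ld_from_freqs(list(pA = 0.3, pB = 0.4, pAB = 0.12))
  expect_equal(e$D, 0)
  expect_equal(e$Dprime, 0)
  expect_equal(e$r2, 0)
  # absent haplotype forces |D'| = 1
  e <- ld_from_freqs(list(pA = 0.3, pB = 0.7, pAB = 0.3))
  expect_equal(e$Dprime, 1)
  expect_error(ld_from_freqs(list(pA = 1, pB = 0.5, pAB = 0.5)),
               "undefined")
})

test_that("r2 never exceeds |D'| over random frequency configurations", {
  set.seed(33)
  n <- 20000
  pA <- runif(n, 0.01, 0.99)
  pB <- runif(n, 0.01, 0.99)
  lo <- pmax(0, pA + pB - 1); hi <- pmin(pA, pB)
  pAB <- lo + runif(n) * (hi - lo)
  s <- ldscape:::.ld_stats(pAB, pA, pB)
  expect_true(all(s[, "r2"] <= s[, "Dprime"] + 1e-12))
  expect_true(all(s[, "Dprime"] >= 0 & s[, "Dprime"] <= 1))
  expect_true(all(s[, "r2"] >= 0 & s[, "r2"] <= 1))
})

test_that("|D'| and r2 are invariant to marker order and allele relabeling", {
  set.seed(34)
  for (i in 1:25) {
    cnt <- matrix(rpois(9, 3), 3, 3)
    n <- sum(cnt)
    pA <- (2 * sum(cnt[3, ]) + sum(cnt[2, ])) / (2 * n)
    pB <- (2 * sum(cnt[, 3]) + sum(cnt[, 2])) / (2 * n)
    if (n < 2 || pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) next
    base <- ld_from_freqs(em_haplotype_freqs(cnt))
    swapped <- ld_from_freqs(em_haplotype_freqs(t(cnt)))
    relab <- ld_from_freqs(em_haplotype_freqs(cnt[3:1, ]))
    expect_equal(swapped$Dprime, base$Dprime, tolerance = 1e-7)
    expect_equal(swapped$r2, base$r2, tolerance = 1e-7)
    expect_equal(relab$Dprime, base$Dprime, tolerance = 1e-7)
    expect_equal(relab$r2, base$r2, tolerance = 1e-7)
  }
})

test_that("|D'| confidence interval behaves across information regimes", {
  # overwhelming complete LD: tight interval at the top
  ci <- dprime_confidence_interval(tab3(n22 = 50, n00 = 50))
  expect_gt(ci["lower"], 0.98)
  expect_equal(unname(ci["upper"]), 1)
  # equilibrium fixture, n = 500 balanced: upper bound well below 0.90
  set.seed(35)
  gA <- rbinom(500, 2, 0.5); gB <- rbinom(500, 2, 0.5)
  ci <- dprime_confidence_interval(two_locus_counts(gA, gB))
  expect_lt(ci["upper"], 0.90)
  # sparse table: wide interval
  ci <- dprime_confidence_interval(tab3(n22 = 1, n11 = 1))
  expect_lt(ci["lower"], 0.5)
  expect_gt(ci["upper"], 0.95)
})

test_that("pairwise_ld pair counts follow the mode and skips are logged", {
  set.seed(36)
  m <- 8
  geno <- matrix(rbinom(50 * m, 2, 0.4), 50, m)
  map <- data.frame(chrom = "1", id = paste0("m", 1:m),
                    pos = seq_len(m) * 1000L)
  g <- geno_matrix(geno, map)
  expect_equal(nrow(pairwise_ld(g, "all")), m * (m - 1) / 2)
  expect_equal(nrow(pairwise_ld(g, "adjacent")), m - 1)
  # a marker monomorphic after missingness: its pairs are skipped
  geno2 <- geno
  geno2[, 2] <- c(rep(2L, 49), NA)
  g2 <- geno_matrix(geno2, map)
  est <- pairwise_ld(g2, "all")
  expect_equal(nrow(est), (m - 1) * (m - 2) / 2)
  expect_equal(attr(est, "n_skipped"), m - 1L)
  expect_false(any(est$id1 == "m2" | est$id2 == "m2"))
})

test_that("pairs never span chromosomes", {
  set.seed(37)
  geno <- matrix(rbinom(40 * 6, 2, 0.5), 40, 6)
  map <- data.frame(chrom = rep(c("1", "2"), each = 3),
                    id = paste0("m", 1:6), pos = rep(c(1L, 2L, 3L) * 100L, 2))
  est <- pairwise_ld(geno_matrix(geno, map), "all")
  expect_equal(nrow(est), 6)   # 2 x choose(3, 2)
  lookup <- setNames(map$chrom, map$id)
  expect_true(all(lookup[est$id1] == lookup[est$id2]))
})
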