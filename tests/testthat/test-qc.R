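test_that("HWE chi-square matches hand values at exact and extreme tables", {
  r <- hwe_chi_square(25, 50, 25)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  r <- hwe_chi_square(50, 0, 50)   # all homozygote, expected (25,50,25)
  expect_equal(r$chi2, 100)
  expect_lt(r$p, 1e-20)
  r <- hwe_chi_square(0, 100, 0)   # all heterozygote, symmetric case
  expect_equal(r$chi2, 100)
})

test_that("HWE chi-square agrees with stats::chisq.test on random tables", {
  set.seed(101)
  for (i in 1:1000) {
    k <- as.vector(stats::rmultinom(1, sample(10:200, 1),
                                    prob = runif(3, 0.05, 1)))
    p <- (2 * k[1] + k[2]) / (2 * sum(k))
    if (p <= 0 || p >= 1) next
    mine <- hwe_chi_square(k[1], k[2], k[3])
    ref <- suppressWarnings(
      stats::chisq.test(k, p = c(p^2, 2 * p * (1 - p), (1 - p)^2)))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
  }
  # monomorphic: test undefined
  r <- hwe_chi_square(10, 0, 0)
  expect_true(is.na(r$chi2))
})

test_that("run_qc applies filters in order with a correct audit report", {
  # 10 markers: 3 designed failures (one per filter), 7 clean markers at
  # exact Hardy-Weinberg proportions (p = 0.4: 16 AA, 48 Aa, 36 aa)
  n <- 100
  clean <- function() c(rep(2L, 16), rep(1L, 48), rep(0L, 36))
  geno <- cbind(
    clean(), clean(), clean(),
    {x <- clean(); x[1:20] <- NA; x},              # call rate 0.80
    c(rep(1L, 4), rep(0L, 96)),                    # MAF 0.02
    c(rep(2L, 50), rep(0L, 50)),                   # extreme HWE failure
    clean(), clean(), clean(), clean())
  map <- data.frame(chrom = rep(c("1", "2"), each = 5),
                    id = paste0("m", 1:10),
                    pos = rep(seq(100L, 500L, by = 100L), 2))
  g <- geno_matrix(geno, map)
  res <- run_qc(g, qc_config())
  rep <- res$report
  expect_equal(rep$n_removed_call_rate, 1L)
  expect_equal(rep$n_removed_maf, 1L)
  expect_equal(rep$n_removed_hwe, 1L)
  expect_equal(rep$n_snps_after, 7L)
  # per-chromosome conservation: before - removed = after
  pc <- rep$per_chromosome
  expect_equal(pc$snps_before - pc$snps_removed, pc$snps_after)
  expect_equal(sum(pc$snps_after), rep$n_snps_after)
})

test_that("samples below the call-rate threshold are removed", {
  set.seed(8)
  geno <- matrix(rbinom(200, 2, 0.5), 10, 20)
  geno[1, 1:10] <- NA   # sample 1 call rate 0.5
  map <- data.frame(chrom = "1", id = paste0("m", 1:20),
                    pos = seq_len(20) * 100L)
  res <- run_qc(geno_matrix(geno, map), qc_config())
  expect_equal(res$report$n_samples_removed, 1L)
  expect_equal(nrow(res$genotypes$geno), 9L)
})

test_that("non-autosomal markers are dropped first", {
  geno <- matrix(rbinom(60, 2, 0.5), 10, 6)
  map <- data.frame(chrom = c("1", "1", "X", "MT", "2", "2"),
                    id = paste0("m", 1:6),
                    pos = c(100L, 200L, 100L, 100L, 100L, 200L))
  res <- run_qc(geno_matrix(geno, map), qc_config(maf_min = 0,
                                                  hwe_p_min = 0))
  expect_equal(res$report$n_removed_nonautosomal, 2L)
  expect_false(any(res$genotypes$map$chrom %in% c("X", "MT")))
})

test_that("QC is idempotent on its own output", {
  # panel-sized fixture: with thousands of markers, dropping a few SNPs
  # leaves sample call rates essentially unchanged, so a second pass
  # removes nothing
  set.seed(9)
  m <- 1500
  geno <- matrix(rbinom(100 * m, 2, runif(m, 0.02, 0.5)), 100, m,
                 byrow = TRUE)
  geno[sample(length(geno), round(0.02 * length(geno)))] <- NA
  map <- data.frame(chrom = rep(c("1", "2", "3"), each = m / 3),
                    id = paste0("m", 1:m),
                    pos = rep(seq_len(m / 3) * 1000L, 3))
  first <- run_qc(geno_matrix(geno, map), qc_config())
  second <- run_qc(first$genotypes, qc_config())
  expect_equal(second$report$n_samples_removed, 0L)
  expect_equal(second$report$n_snps_after, first$report$n_snps_after)
  expect_identical(second$genotypes$geno, first$genotypes$geno)
})

test_that("empty-output QC errors are explicit", {
  geno <- matrix(c(2L, 2L, 2L, 2L), 2, 2)   # monomorphic everywhere
  map <- data.frame(chrom = "1", id = c("m1", "m2"), pos = c(1L, 2L))
  expect_error(run_qc(geno_matrix(geno, map), qc_config()),
               "empty after QC")
})

test_that("QC config round-trips through a key=value file", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "maf_min=0.1", "hwe_p_min=0.05"), path)
  cfg <- read_qc_config(path)
  expect_equal(cfg$maf_min, 0.1)
  expect_equal(cfg$hwe_p_min, 0.05)
  expect_equal(cfg$snp_call_rate_min, 0.9)  # default preserved
  writeLines("nonsense=1", path)
  expect_error(read_qc_config(path), "unknown")
})
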