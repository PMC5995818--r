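test_that("ped/map round-trip is the identity on dosages and map", {
  g <- make_tiny_geno()
  ped <- withr::local_tempfile(fileext = ".ped")
  mp <- withr::local_tempfile(fileext = ".map")
  write_ped_map(g, ped, mp)
  g2 <- read_ped_map(ped, mp)
  expect_identical(unname(g2$geno), unname(g$geno))
  expect_equal(g2$map$pos, g$map$pos)
  expect_equal(g2$map$chrom, g$map$chrom)
  expect_equal(g2$ids, g$ids)
  # byte stability on re-write
  ped2 <- withr::local_tempfile(fileext = ".ped")
  mp2 <- withr::local_tempfile(fileext = ".map")
  write_ped_map(g2, ped2, mp2)
  expect_identical(readLines(ped2), readLines(ped))
  expect_identical(readLines(mp2), readLines(mp))
})

test_that("ped round-trip preserves orientation-invariant statistics for
           arbitrary fixtures", {
  set.seed(41)
  geno <- matrix(rbinom(60, 2, 0.5), 6, 10)
  map <- data.frame(chrom = "1", id = paste0("m", 1:10),
                    pos = (1:10) * 500L)
  g <- geno_matrix(geno, map)
  ped <- withr::local_tempfile(fileext = ".ped")
  mp <- withr::local_tempfile(fileext = ".map")
  write_ped_map(g, ped, mp)
  g2 <- read_ped_map(ped, mp)
  expect_equal(allele_stats(g2)$maf, allele_stats(g)$maf)
  expect_equal(allele_stats(g2)$call_rate, allele_stats(g)$call_rate)
  # genotype content identical up to per-marker allele orientation
  ok <- vapply(seq_len(ncol(geno)), function(j) {
    a <- unname(g$geno[, j]); b <- unname(g2$geno[, j])
    identical(a, b) || identical(a, 2L - b)
  }, logical(1))
  expect_true(all(ok))
})

test_that("ped parsing: missing code and allele errors", {
  ped <- withr::local_tempfile(fileext = ".ped")
  mp <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 snpA 0 100", "1 snpB 0 200"), mp)
  writeLines(c("F i1 0 0 0 -9 A A C G",
               "F i2 0 0 0 -9 0 0 C C"), ped)
  g <- read_ped_map(ped, mp)
  expect_true(is.na(g$geno[2, 1]))        # "0 0" -> missing
  expect_equal(g$geno[1, 1], 2L)          # AA at first-seen allele A
  # three alleles at snpB -> error naming the marker
  writeLines(c("F i1 0 0 0 -9 A A C G",
               "F i2 0 0 0 -9 A A T T"), ped)
  expect_error(read_ped_map(ped, mp), "snpB")
  # row-length mismatch
  writeLines(c("F i1 0 0 0 -9 A A"), ped)
  expect_error(read_ped_map(ped, mp), "does not match")
})

test_that("VCF coding table, multiallelic skipping and round-trip", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("1", "100", "v1", "A", "C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "./.", sep = "\t"),
    paste("1", "200", "v2", "G", "T,C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/2", "2/2", sep = "\t"),
    paste("1", "300", "v3", "G", "T", ".", "PASS", ".", "GT",
          "0|0", "0|1", "1|1", "1|0", sep = "\t")), vcf)
  g <- read_vcf(vcf)
  expect_equal(attr(g, "n_skipped"), 1L)  # the multiallelic record
  expect_equal(ncol(g$geno), 2L)
  expect_equal(unname(g$geno[, 1]), c(2L, 1L, 0L, NA))
  expect_equal(unname(g$geno[, 2]), c(2L, 1L, 0L, 1L))  # | accepted
  # round-trip through write_vcf
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, out)
  g2 <- read_vcf(out)
  expect_identical(unname(g2$geno), unname(g$geno))
  expect_equal(g2$map$pos, g$map$pos)
})

test_that("VCF without GT errors", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("1", "100", "v1", "A", "C", ".", "PASS", ".", "DP", "10",
          sep = "\t")), vcf)
  expect_error(read_vcf(vcf), "GT")
})

test_that("allele_stats matches hand counts and flags all-missing markers", {
  st <- allele_stats(matrix(c(0L, 1L, 2L), ncol = 1))
  expect_equal(st$p_A, 0.5)
  expect_equal(st$maf, 0.5)
  st <- allele_stats(matrix(c(2L, 2L, 2L, 2L), ncol = 1))
  expect_equal(st$p_A, 1)
  expect_equal(st$maf, 0)
  st <- allele_stats(matrix(c(2L, 1L, NA, 0L), ncol = 1))
  expect_equal(st$call_rate, 0.75)
  expect_equal(st$p_A, 0.5)
  st <- allele_stats(matrix(NA_integer_, 3, 1))
  expect_true(st$all_missing)
  expect_true(is.na(st$p_A))
})

test_that("dosage-based frequency equals the haplotype-count route on a
           phase-known fixture", {
  set.seed(42)
  h1 <- matrix(rbinom(200, 1, 0.3), 20, 10)
  h2 <- matrix(rbinom(200, 1, 0.3), 20, 10)
  g <- geno_from_haplotypes(h1, h2)
  st <- allele_stats(g)
  expect_equal(st$p_A, colMeans(rbind(h1, h2)), tolerance = 1e-12)
})
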