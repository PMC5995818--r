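#' Quality-control configuration
#'
#' Thresholds for the genotype QC protocol. All "lower than" comparisons are
#' strict: a sample or SNP is removed when its statistic is strictly below
#' the threshold.
#'
#' @param sample_call_rate_min minimum sample call rate (default 0.90).
#' @param snp_call_rate_min minimum SNP call rate (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_p_min minimum Hardy-Weinberg chi-square p-value (default 0.1).
#' @param autosomes_only drop markers whose chromosome is not in
#'   \code{autosomes} (default TRUE).
#' @param autosomes chromosome whitelist; \code{NULL} means "any label that
#'   parses as a positive integer" (the usual autosome labelling).
#' @return A list of class \code{qc_config}.
#' @export
qc_config <- function(sample_call_rate_min = 0.90,
                      snp_call_rate_min = 0.90,
                      maf_min = 0.05,
                      hwe_p_min = 0.1,
                      autosomes_only = TRUE,
                      autosomes = NULL) {
  thr <- c(sample_call_rate_min, snp_call_rate_min, maf_min, hwe_p_min)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 snp_call_rate_min = snp_call_rate_min,
                 maf_min = maf_min,
                 hwe_p_min = hwe_p_min,
                 autosomes_only = autosomes_only,
                 autosomes = autosomes),
            class = "qc_config")
}

#' Read a QC configuration from a key=value or YAML file
#'
#' @param path a flat \code{key=value} file or a YAML file (by extension
#'   .yml/.yaml). Unknown keys are rejected.
#' @return A \code{qc_config}.
#' @export
read_qc_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(x) type.convert(trimws(x[2]), as.is = TRUE))
    names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  }
  known <- names(formals(qc_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown QC config keys: ", paste(bad, collapse = ","))
  do.call(qc_config, vals)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Goodness-of-fit chi-square test (1 df, no continuity correction) of
#' genotype counts against Hardy-Weinberg proportions computed from the
#' sample allele frequency. Vectorised over count triples. For a
#' monomorphic marker the test is undefined and both statistic and p-value
#' are \code{NA} (no evidence against HWE).
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (vectors recycle).
#' @return data.frame with columns \code{chi2} and \code{p}.
#' @export
hwe_chi_square <- function(n_AA, n_Aa, n_aa) {
  k <- cbind(n_AA, n_Aa, n_aa)
  if (any(k < 0)) stop("genotype counts must be nonnegative")
  n <- rowSums(k)
  if (any(n < 1)) stop("total genotype count must be >= 1")
  p <- (2 * k[, 1] + k[, 2]) / (2 * n)
  mono <- p <= 0 | p >= 1
  e <- cbind(n * p^2, n * 2 * p * (1 - p), n * (1 - p)^2)
  chi2 <- rowSums((k - e)^2 / e)
  chi2[mono] <- NA_real_
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(chi2 = chi2, p = pval)
}

#' Run the genotype quality-control protocol
#'
#' Filters are applied in a fixed order so the audit report is
#' deterministic: (1) non-autosomal markers are dropped; (2) samples with
#' call rate below threshold are dropped; (3) marker statistics are
#' recomputed on the retained samples; (4) SNPs are removed by call rate,
#' then MAF, then the HWE chi-square p-value. A SNP failing several filters
#' is attributed to the first in that order. Running QC on its own output
#' removes nothing further.
#'
#' @param genotypes a \code{geno_matrix}.
#' @param config a \code{qc_config}.
#' @return list with \code{genotypes} (filtered \code{geno_matrix}) and
#'   \code{report} (class \code{qc_report}): removed counts per filter, and
#'   a per-chromosome before/after SNP table.
#' @export
run_qc <- function(genotypes, config = qc_config()) {
  g <- genotypes
  chrom_before <- table(factor(g$map$chrom, levels = unique(g$map$chrom)))

  # (1) autosome filter
  if (isTRUE(config$autosomes_only)) {
    keep_chrom <- if (is.null(config$autosomes)) {
      grepl("^[0-9]+$", g$map$chrom)
    } else g$map$chrom %in% as.character(config$autosomes)
  } else keep_chrom <- rep(TRUE, ncol(g$geno))
  n_nonautosomal <- sum(!keep_chrom)
  g <- subset_geno(g, markers = which(keep_chrom))
  if (ncol(g$geno) == 0L) stop("empty after QC: no autosomal markers")

  # (2) sample call rate
  scr <- rowMeans(!is.na(g$geno))
  keep_s <- scr >= config$sample_call_rate_min
  n_samples_removed <- sum(!keep_s)
  if (!any(keep_s)) stop("empty after QC: all samples removed")
  g <- subset_geno(g, individuals = which(keep_s))

  # (3) recompute marker stats on retained samples
  st <- allele_stats(g)

  # (4) SNP filters, first failing filter attributed
  fail_cr <- st$call_rate < config$snp_call_rate_min
  fail_maf <- !fail_cr & (st$all_missing | is.na(st$maf) |
                            st$maf < config$maf_min)
  hwe <- hwe_chi_square(st$n_AA, st$n_Aa, st$n_aa)
  hwe_fail_raw <- !is.na(hwe$p) & hwe$p < config$hwe_p_min
  fail_hwe <- !fail_cr & !fail_maf & hwe_fail_raw
  keep_m <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep_m)) stop("empty after QC: all markers removed")
  out <- subset_geno(g, markers = which(keep_m))

  lev <- names(chrom_before)
  chrom_after <- table(factor(out$map$chrom, levels = lev))
  per_chrom <- data.frame(chrom = lev,
                          snps_before = as.integer(chrom_before),
                          snps_after = as.integer(chrom_after),
                          stringsAsFactors = FALSE)
  per_chrom$snps_removed <- per_chrom$snps_before - per_chrom$snps_after

  report <- structure(list(
    n_samples_before = length(genotypes$ids),
    n_samples_removed = n_samples_removed,
    n_samples_after = length(out$ids),
    n_snps_before = ncol(genotypes$geno),
    n_removed_nonautosomal = n_nonautosomal,
    n_removed_call_rate = sum(fail_cr),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_snps_after = ncol(out$geno),
    per_chromosome = per_chrom,
    config = config), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  samples: %d -> %d (%d removed by call rate)\n",
              x$n_samples_before, x$n_samples_after, x$n_samples_removed))
  cat(sprintf("  SNPs: %d -> %d\n", x$n_snps_before, x$n_snps_after))
  cat(sprintf("    non-autosomal: %d, call rate: %d, MAF: %d, HWE: %d\n",
              x$n_removed_nonautosomal, x$n_removed_call_rate,
              x$n_removed_maf, x$n_removed_hwe))
  invisible(x)
}
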