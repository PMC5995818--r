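#' Excess-homozygosity inbreeding coefficients
#'
#' Method-of-moments inbreeding coefficient
#' \eqn{F_i = (O_i - E_i)/(L_i - E_i)}, where \eqn{O_i} is the number of
#' observed homozygous loci of individual i, \eqn{L_i} its number of
#' non-missing genotyped loci and \eqn{E_i} the expected number of
#' homozygous loci under Hardy-Weinberg proportions at the sample allele
#' frequencies, summed over that individual's non-missing loci. By default
#' the expectation uses the small-sample-corrected per-locus heterozygosity
#' \eqn{2p(1-p)\,2n/(2n-1)} (the estimator used by common SNP toolkits),
#' which makes F unbiased around 0 in an unrelated sample;
#' \code{sample_correction = FALSE} gives the plain \eqn{2p(1-p)} form.
#' Negative F occurs exactly when fewer homozygous loci are observed than
#' expected.
#'
#' @param genotypes a \code{geno_matrix}.
#' @param freqs optional allele-A frequency vector (defaults to in-sample
#'   estimates).
#' @param sample_correction apply the 2n/(2n-1) factor (default TRUE).
#' @return list of class \code{inbreeding_result}: \code{table} (data.frame
#'   id, O, E, L, F, degenerate) and \code{mean_F} over individuals with
#'   defined F.
#' @export
inbreeding <- function(genotypes, freqs = NULL, sample_correction = TRUE) {
  g <- genotypes
  st <- allele_stats(g)
  if (is.null(freqs)) freqs <- st$p_A
  if (length(freqs) != ncol(g$geno))
    stop("freqs must have one entry per marker")
  nonmiss_per_marker <- st$n_AA + st$n_Aa + st$n_aa
  corr <- if (sample_correction) {
    ifelse(nonmiss_per_marker > 0,
           2 * nonmiss_per_marker / (2 * nonmiss_per_marker - 1), 1)
  } else rep(1, length(freqs))
  het_exp <- 2 * freqs * (1 - freqs) * corr   # expected het per locus
  hom_exp <- 1 - het_exp
  obs <- !is.na(g$geno)
  L <- rowSums(obs)
  if (any(L < 1)) stop("every individual needs at least one genotyped locus")
  O <- rowSums(obs & (g$geno == 0L | g$geno == 2L), na.rm = TRUE)
  hom_exp[is.na(hom_exp)] <- 0   # all-missing markers contribute nothing
  E <- as.vector(obs %*% hom_exp)
  degenerate <- abs(L - E) < .Machine$double.eps^0.5
  F_i <- ifelse(degenerate, NA_real_, (O - E) / (L - E))
  tab <- data.frame(id = g$ids, O = O, E = E, L = L, F = F_i,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, mean_F = mean(F_i, na.rm = TRUE)),
            class = "inbreeding_result")
}

#' @export
print.inbreeding_result <- function(x, ...) {
  cat(sprintf("inbreeding over %d individuals: mean F = %.4f\n",
              nrow(x$table), x$mean_F))
  invisible(x)
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' Centers dosages by twice the allele frequency and scales by the summed
#' heterozygosity: \eqn{G = ZZ'/(2\sum_j p_j(1-p_j))} with
#' \eqn{Z_{ij} = x_{ij} - 2p_j}. Frequencies default to in-sample
#' estimates. Markers monomorphic in the sample are dropped (counted in
#' \code{attr(G, "n_dropped")}); missing dosages enter Z as 0 (that is, at
#' their centered expectation).
#'
#' @param genotypes a \code{geno_matrix}.
#' @param freqs optional allele-A frequency vector.
#' @return n x n symmetric matrix of class \code{grm} with the frequency
#'   vector attached as \code{attr(G, "freqs")}.
#' @export
vanraden_grm <- function(genotypes, freqs = NULL) {
  g <- genotypes
  st <- allele_stats(g)
  if (is.null(freqs)) freqs <- st$p_A
  if (length(freqs) != ncol(g$geno))
    stop("freqs must have one entry per marker")
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  n_dropped <- sum(!poly)
  if (!any(poly)) stop("all markers monomorphic; G undefined")
  X <- g$geno[, poly, drop = FALSE]
  p <- freqs[poly]
  Z <- sweep(X, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(g$ids, g$ids)
  attr(G, "freqs") <- p
  attr(G, "n_dropped") <- n_dropped
  class(G) <- c("grm", class(G))
  G
}

#' Distribution summary of genomic relationships
#'
#' Summarizes the strict upper triangle of a relationship matrix: mean, SD,
#' range, and the number of pairs falling near the half-sib (0.25),
#' full-sib (0.5) and duplicate/twin (1.0) relationship degrees.
#'
#' @param G relationship matrix from \code{\link{vanraden_grm}}.
#' @param window half-width of the "near" windows (default 0.1).
#' @return data.frame with one row: \code{n_pairs}, \code{mean}, \code{sd},
#'   \code{min}, \code{max}, \code{n_near_0.25}, \code{n_near_0.5},
#'   \code{n_near_1.0}, \code{mean_diag}.
#' @export
relationship_summary <- function(G, window = 0.1) {
  if (nrow(G) < 2L) stop("need at least 2 individuals")
  v <- G[upper.tri(G)]
  data.frame(n_pairs = length(v), mean = mean(v), sd = stats::sd(v),
             min = min(v), max = max(v),
             n_near_0.25 = sum(abs(v - 0.25) <= window),
             n_near_0.5 = sum(abs(v - 0.5) <= window),
             n_near_1.0 = sum(abs(v - 1.0) <= window),
             mean_diag = mean(diag(G)))
}

#' Write inbreeding and G-matrix tables
#'
#' @param inb an \code{inbreeding_result}.
#' @param G a \code{grm} matrix.
#' @param f_path,g_path output TSV paths; the G matrix is written as a
#'   triplet table (i, j, value) over the lower triangle including the
#'   diagonal.
#' @return Invisibly, the paths written.
#' @export
write_relatedness_tables <- function(inb, G, f_path, g_path) {
  utils::write.table(format(inb$table, digits = 8, trim = TRUE),
                     f_path, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  trip <- data.frame(id_i = rownames(G)[idx[, 1]],
                     id_j = colnames(G)[idx[, 2]],
                     value = signif(G[idx], 8))
  utils::write.table(trip, g_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(f_path, g_path))
}
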