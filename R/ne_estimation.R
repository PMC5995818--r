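#' Effective-population-size estimation configuration
#'
#' @param cM_per_Mb genetic-map scaling; 1 cM per Mb by default.
#' @param alpha mutation adjustment in the Sved inversion: 1 (no mutation),
#'   2, or 2.2 (mutation-drift equilibrium). Default 2.2.
#' @param sample_size_correction subtract the sampling inflation of the EM
#'   r-squared estimate — one over the number of sampled chromosomes,
#'   1/(2 n) for n diploids — from each bin's mean r-squared before
#'   inversion (default TRUE).
#' @param bin_edges_mb distance bin edges in Mb (default 0.05-Mb-wide bins
#'   from 0.05 to 4 Mb).
#' @param min_pairs_per_bin drop bins with fewer pairs (default 50).
#' @return list of class \code{ne_config}.
#' @export
ne_config <- function(cM_per_Mb = 1.0, alpha = 2.2,
                      sample_size_correction = TRUE,
                      bin_edges_mb = seq(0.05, 4, by = 0.05),
                      min_pairs_per_bin = 50L) {
  if (!alpha %in% c(1, 2, 2.2))
    stop("alpha must be one of 1, 2, 2.2")
  if (is.unsorted(bin_edges_mb, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  structure(list(cM_per_Mb = cM_per_Mb, alpha = alpha,
                 sample_size_correction = sample_size_correction,
                 bin_edges_mb = bin_edges_mb,
                 min_pairs_per_bin = as.integer(min_pairs_per_bin)),
            class = "ne_config")
}

#' Physical to genetic distance
#'
#' Converts base pairs to Morgans at a constant cM-per-Mb rate
#' (1 Mb = 1 cM = 0.01 Morgan by default).
#'
#' @param distance_bp physical distance(s), bp, nonnegative.
#' @param cM_per_Mb map scaling (default 1).
#' @return distance in Morgans.
#' @export
physical_to_genetic <- function(distance_bp, cM_per_Mb = 1.0) {
  if (any(distance_bp < 0)) stop("distance must be nonnegative")
  (distance_bp / 1e6) * cM_per_Mb / 100
}

#' Sved expectation of r-squared
#'
#' \eqn{E[r^2] = 1/(1 + 4 N_e c)} for recombination rate c (Morgans).
#'
#' @param Ne effective population size (> 0).
#' @param c recombination rate(s) in Morgans (>= 0).
#' @return expected r-squared.
#' @export
sved_expected_r2 <- function(Ne, c) {
  if (any(Ne <= 0)) stop("Ne must be positive")
  if (any(c < 0)) stop("c must be nonnegative")
  1 / (1 + 4 * Ne * c)
}

#' Effective population size from one distance bin
#'
#' Inverts the Sved relation for a bin's mean r-squared:
#' \eqn{N_e = (4c)^{-1}(1/r^2_{adj} - \alpha)}, with
#' \eqn{r^2_{adj} = \bar{r}^2 - 1/n} when the sample-size correction is on.
#' A bin whose adjusted r-squared leaves the open interval (0, 1), or whose
#' resulting \eqn{N_e} is nonpositive, is flagged unusable
#' (\code{usable = FALSE}, \code{Ne = NA}).
#'
#' @param mean_r2 mean r-squared of the bin.
#' @param c recombination rate at the bin's mean distance (Morgans, > 0).
#' @param alpha mutation adjustment (1, 2 or 2.2).
#' @param n_samples number of sampled individuals (used by the correction).
#' @param correction apply the 1/n correction (default TRUE).
#' @return list: \code{Ne}, \code{adj_r2}, \code{usable}.
#' @export
ne_from_bin <- function(mean_r2, c, alpha = 2.2, n_samples = NULL,
                        correction = TRUE) {
  if (c <= 0) stop("c must be positive")
  adj <- mean_r2
  if (correction) {
    if (is.null(n_samples)) stop("n_samples needed for the 1/n correction")
    adj <- mean_r2 - 1 / n_samples
  }
  if (!is.finite(adj) || adj <= 0 || adj >= 1)
    return(list(Ne = NA_real_, adj_r2 = adj, usable = FALSE))
  Ne <- (1 / (4 * c)) * (1 / adj - alpha)
  if (Ne <= 0) return(list(Ne = NA_real_, adj_r2 = adj, usable = FALSE))
  list(Ne = Ne, adj_r2 = adj, usable = TRUE)
}

#' Effective-population-size trajectory from LD decay
#'
#' Bins within-chromosome pairwise LD estimates by physical distance,
#' converts each bin's mean distance to a recombination rate c at the
#' configured cM/Mb, maps c to generation \eqn{t = 1/(2c)} (rounded to the
#' nearest integer), and inverts the Sved relation per bin. Per-chromosome
#' \eqn{N_e} is the harmonic mean over that chromosome's usable bins; the
#' "recent" \eqn{N_e} is the usable bin with the largest c (shortest
#' look-back). When the sample-size correction is on, the subtracted term
#' is one over the number of sampled chromosomes (2 per diploid), the
#' measured inflation of EM-based r-squared estimates.
#'
#' @param estimates an \code{ld_estimates} data.frame (all-pairwise mode).
#' @param config an \code{ne_config}.
#' @param n_samples number of sampled diploid individuals; defaults to
#'   \code{attr(estimates, "n_samples")}.
#' @return list of class \code{ne_trajectory}: \code{bins} (data.frame
#'   bin_lo_mb, bin_hi_mb, n_pairs, mean_dist_mb, c, t, mean_r2, adj_r2,
#'   Ne, usable), \code{per_chromosome} (chrom, n_bins, Ne_harmonic),
#'   \code{recent_Ne}, \code{config}.
#' @export
ne_trajectory <- function(estimates, config = ne_config(),
                          n_samples = NULL) {
  e <- as.data.frame(estimates)
  if (is.null(n_samples)) n_samples <- attr(estimates, "n_samples")
  if (config$sample_size_correction && is.null(n_samples))
    stop("n_samples unknown; pass it or disable the correction")
  bin_one <- function(d) {
    tab <- bin_by_distance(d, config$bin_edges_mb)
    tab <- tab[tab$n_pairs >= config$min_pairs_per_bin, , drop = FALSE]
    if (nrow(tab) == 0L) return(tab)
    tab$c <- physical_to_genetic(tab$mean_dist_mb * 1e6, config$cM_per_Mb)
    tab$t <- as.integer(round(1 / (2 * tab$c)))
    r <- lapply(seq_len(nrow(tab)), function(i)
      ne_from_bin(tab$mean_r2[i], tab$c[i], alpha = config$alpha,
                  n_samples = 2 * n_samples,   # sampled chromosomes
                  correction = config$sample_size_correction))
    tab$adj_r2 <- vapply(r, `[[`, numeric(1), "adj_r2")
    tab$Ne <- vapply(r, `[[`, numeric(1), "Ne")
    tab$usable <- vapply(r, `[[`, logical(1), "usable")
    tab
  }
  pooled <- bin_one(e)
  usable <- pooled[pooled$usable, , drop = FALSE]
  if (nrow(usable) == 0L) stop("no usable distance bins for Ne estimation")
  recent <- usable[which.max(usable$c), ]
  per_chrom <- do.call(rbind, lapply(unique(e$chrom), function(ch) {
    tab <- bin_one(e[e$chrom == ch, , drop = FALSE])
    tab <- tab[tab$usable, , drop = FALSE]
    data.frame(chrom = ch, n_bins = nrow(tab),
               Ne_harmonic = if (nrow(tab)) harmonic_mean(tab$Ne)
                             else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(bins = pooled, per_chromosome = per_chrom,
                 recent_Ne = recent$Ne, recent_t = recent$t,
                 recent_c = recent$c, config = config,
                 n_samples = n_samples),
            class = "ne_trajectory")
}

#' Harmonic mean
#'
#' @param x positive values.
#' @return \eqn{n / \sum 1/x_i}.
#' @export
harmonic_mean <- function(x) {
  if (any(x <= 0)) stop("harmonic mean needs positive values")
  length(x) / sum(1 / x)
}

#' @export
print.ne_trajectory <- function(x, ...) {
  u <- x$bins[x$bins$usable, ]
  cat(sprintf("Ne trajectory: %d usable bins, t in [%d, %d]\n",
              nrow(u), min(u$t), max(u$t)))
  cat(sprintf("  recent Ne (t = %d): %.1f\n", x$recent_t, x$recent_Ne))
  invisible(x)
}

#' Drift-recombination expectation of squared disequilibrium
#'
#' Closed-form expectation of \eqn{D^2} at initial frequencies
#' \eqn{p_0, q_0} as a function of the inbreeding coefficient F:
#' \deqn{E(D^2) = \frac{1}{15} p_0(1-p_0) q_0(1-q_0)
#'   [6(1-F) - 5(1-F)^3 - (1-F)^6].}
#' Zero at both F = 0 and F = 1.
#'
#' @param p0,q0 initial allele frequencies in (0, 1).
#' @param F inbreeding coefficient in [0, 1].
#' @return expected squared disequilibrium.
#' @export
hill_robertson_expected_d2 <- function(p0, q0, F) {
  stopifnot(all(p0 > 0 & p0 < 1), all(q0 > 0 & q0 < 1),
            all(F >= 0 & F <= 1))
  g <- 1 - F
  (1 / 15) * p0 * (1 - p0) * q0 * (1 - q0) * (6 * g - 5 * g^3 - g^6)
}

#' One-generation recursion for expected disequilibrium
#'
#' \eqn{E(D_t) = (1 - c)(1 - 1/(2N_e)) E(D_{t-1})}: disequilibrium decays
#' each generation by recombination and drift-sampling.
#'
#' @param D_prev expected disequilibrium at the previous generation.
#' @param c recombination rate in [0, 0.5].
#' @param Ne effective population size (> 0.5).
#' @return expected disequilibrium after one generation.
#' @export
sved_recursion_step <- function(D_prev, c, Ne) {
  stopifnot(all(c >= 0 & c <= 0.5), all(Ne > 0.5))
  (1 - c) * (1 - 1 / (2 * Ne)) * D_prev
}

#' Correlation between predicted and observed squared disequilibrium
#'
#' For each chromosome, predicts \eqn{E(D^2)} from the chromosome's mean
#' allele frequency (used for both loci) and its mean inbreeding
#' coefficient via \code{\link{hill_robertson_expected_d2}}, and correlates
#' the predictions with the observed per-chromosome mean \eqn{D^2} of the
#' LD estimates.
#'
#' @param estimates an \code{ld_estimates} data.frame (adjacent or
#'   all-pairwise mode).
#' @param genotypes the \code{geno_matrix} the estimates came from; used
#'   for per-chromosome mean allele frequencies and per-chromosome mean F
#'   (inbreeding recomputed on each chromosome's markers).
#' @return list: \code{correlation}, \code{table} (chrom, mean_freq, F,
#'   predicted_d2, observed_d2). \code{correlation} is \code{NA} with a
#'   warning when either series is constant; fewer than 3 chromosomes is an
#'   error.
#' @export
d2_f_correlation <- function(estimates, genotypes) {
  e <- as.data.frame(estimates)
  chroms <- unique(e$chrom)
  if (length(chroms) < 3L) stop("need at least 3 chromosomes")
  st <- allele_stats(genotypes)
  tab <- do.call(rbind, lapply(chroms, function(ch) {
    d <- e[e$chrom == ch, ]
    p <- mean(st$maf[st$chrom == ch], na.rm = TRUE)
    F_ch <- inbreeding(subset_geno(genotypes,
                                   markers = which(st$chrom == ch)))$mean_F
    data.frame(chrom = ch, mean_freq = p,
               F = F_ch,
               predicted_d2 = hill_robertson_expected_d2(
                 p, p, min(max(F_ch, 0), 1)),
               observed_d2 = mean(d$D^2),
               stringsAsFactors = FALSE)
  }))
  if (stats::sd(tab$predicted_d2) == 0 || stats::sd(tab$observed_d2) == 0) {
    warning("constant series; correlation undefined")
    return(list(correlation = NA_real_, table = tab))
  }
  list(correlation = stats::cor(tab$predicted_d2, tab$observed_d2),
       table = tab)
}
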