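#' Two-locus genotype counts
#'
#' Cross-tabulates two dosage vectors into the 3x3 table used by the EM
#' haplotype-frequency estimator; only individuals non-missing at both
#' markers are counted.
#'
#' @param d1,d2 dosage vectors in \{0,1,2,NA\} of equal length.
#' @return 3x3 integer matrix \code{n[i+1, j+1]} = individuals with dosage
#'   \code{i} at marker 1 and \code{j} at marker 2.
#' @export
two_locus_counts <- function(d1, d2) {
  ok <- !is.na(d1) & !is.na(d2)
  tab <- table(factor(d1[ok], levels = 0:2), factor(d2[ok], levels = 0:2))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(d1 = 0:2, d2 = 0:2))
  m
}

# Internal vectorised EM over many 3x3 tables.
#
# N: k x 9 matrix of counts in column order
#    n00 n01 n02 n10 n11 n12 n20 n21 n22 (first index = dosage at marker 1).
# One EM run from a given pAB start vector.
.em_run <- function(cAB, cAb, caB, cab, h, twoN, pA, pB, start_pAB,
                    tol, max_iter) {
  k <- length(start_pAB)
  pAB <- start_pAB
  pAb <- pA - pAB
  paB <- pB - pAB
  pab <- 1 - pA - pB + pAB
  iter <- integer(k)
  active <- rep(TRUE, k)
  it <- 0L
  while (any(active) && it < max_iter) {
    it <- it + 1L
    den <- pAB * pab + pAb * paB
    P <- ifelse(den > 0, pAB * pab / den, 0.5)
    nAB <- (cAB + h * P) / twoN
    nAb <- (cAb + h * (1 - P)) / twoN
    naB <- (caB + h * (1 - P)) / twoN
    nab <- (cab + h * P) / twoN
    delta <- pmax(abs(nAB - pAB), abs(nAb - pAb),
                  abs(naB - paB), abs(nab - pab))
    delta[!is.finite(delta)] <- 0  # degenerate (empty) tables: stop iterating
    upd <- active
    pAB[upd] <- nAB[upd]; pAb[upd] <- nAb[upd]
    paB[upd] <- naB[upd]; pab[upd] <- nab[upd]
    iter[upd] <- it
    active <- active & delta >= tol
  }
  list(pAB = pAB, pAb = pAb, paB = paB, pab = pab,
       iter = iter, converged = !active)
}

# vectorised genotype log-likelihood at haplotype frequencies (margins
# implied), one value per table
.geno_loglik <- function(N, pAB, pAb, paB, pab) {
  probs <- cbind(pab^2, 2 * paB * pab, paB^2,
                 2 * pAb * pab, 2 * (pAB * pab + pAb * paB), 2 * pAB * paB,
                 pAb^2, 2 * pAB * pAb, pAB^2)
  rowSums(N * log(pmax(probs, 1e-300)))
}

# Multi-start EM: the linkage-equilibrium start is deterministic but can
# stall on a stationary point when the phase-known genotype counts are
# themselves at equilibrium, so two interior starts bracketing the
# admissible range are run as well and the highest-likelihood solution
# wins (ties, within 1e-9, keep the LE solution). Tables whose only
# evidence is double heterozygotes ("saddle" tables) keep the LE solution
# (D = 0) and are flagged.
# Returns a k x 10 matrix: pAB pAb paB pab pA pB iter converged n saddle.
.em_many <- function(N, tol = 1e-8, max_iter = 1000L) {
  n <- rowSums(N)
  n00 <- N[, 1]; n01 <- N[, 2]; n02 <- N[, 3]
  n10 <- N[, 4]; n11 <- N[, 5]; n12 <- N[, 6]
  n20 <- N[, 7]; n21 <- N[, 8]; n22 <- N[, 9]
  twoN <- 2 * n
  pA <- (2 * (n20 + n21 + n22) + (n10 + n11 + n12)) / twoN
  pB <- (2 * (n02 + n12 + n22) + (n01 + n11 + n21)) / twoN
  # phase-known haplotype contributions
  cAB <- 2 * n22 + n21 + n12
  cAb <- 2 * n20 + n21 + n10
  caB <- 2 * n02 + n01 + n12
  cab <- 2 * n00 + n01 + n10
  h <- n11
  saddle <- (cAB + cAb + caB + cab) == 0 & h > 0
  lo <- pmax(0, pA + pB - 1)
  hi <- pmin(pA, pB)
  starts <- list(pmin(pmax(pA * pB, lo), hi),
                 lo + 0.25 * (hi - lo),
                 lo + 0.75 * (hi - lo))
  runs <- lapply(starts, function(s)
    .em_run(cAB, cAb, caB, cab, h, twoN, pA, pB, s, tol, max_iter))
  # EM approaches a boundary maximum (an absent haplotype) only
  # sublinearly, so the two admissible-range endpoints enter the
  # candidate set directly
  for (s in list(lo, hi)) {
    runs[[length(runs) + 1L]] <-
      list(pAB = s, pAb = pA - s, paB = pB - s, pab = 1 - pA - pB + s,
           iter = rep(0L, length(s)), converged = rep(TRUE, length(s)))
  }
  lls <- vapply(runs, function(r)
    .geno_loglik(N, r$pAB, r$pAb, r$paB, r$pab), numeric(nrow(N)))
  if (nrow(N) == 1L) lls <- matrix(lls, nrow = 1L)
  lls[!is.finite(lls)] <- -Inf   # degenerate tables
  best <- max.col(lls, ties.method = "first")
  # prefer the LE run unless another start is a real improvement;
  # saddle tables always keep the LE (D = 0) solution
  improve <- lls[cbind(seq_len(nrow(N)), best)] - lls[, 1] > 1e-9
  improve[is.na(improve)] <- FALSE
  best[!improve | saddle] <- 1L
  pick <- function(field) {
    out <- runs[[1]][[field]]
    for (s in seq_along(runs)[-1]) {
      sel <- best == s
      out[sel] <- runs[[s]][[field]][sel]
    }
    out
  }
  cbind(pAB = pick("pAB"), pAb = pick("pAb"), paB = pick("paB"),
        pab = pick("pab"), pA = pA, pB = pB, iter = pick("iter"),
        converged = as.numeric(pick("converged")), n = n,
        saddle = as.numeric(saddle))
}

#' EM haplotype-frequency estimation for one marker pair
#'
#' Maximum-likelihood estimation of the four haplotype frequencies from
#' unphased two-locus genotype counts. The double heterozygote is the only
#' ambiguous genotype (AB/ab is indistinguishable from Ab/aB); the E-step
#' splits it in proportion to \eqn{\rho_{AB}\rho_{ab}} vs
#' \eqn{\rho_{Ab}\rho_{aB}}, the M-step re-estimates joints from expected
#' haplotype counts. Iteration starts at linkage equilibrium
#' (\eqn{\rho_{AB} = \rho_A \rho_B}); because that start is a stationary
#' point for some tables, two deterministic interior starts bracketing the
#' admissible range are run as well and the highest-likelihood solution is
#' kept. A table containing only double heterozygotes carries no phase
#' information at all: it keeps the equilibrium solution (D = 0) and is
#' flagged (\code{saddle = TRUE}).
#'
#' @param counts 3x3 matrix from \code{\link{two_locus_counts}}.
#' @param tol convergence tolerance on the largest frequency change
#'   (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return list of class \code{hap_freqs}: \code{pAB}, \code{pAb},
#'   \code{paB}, \code{pab}, margins \code{pA}, \code{pB}, \code{iter},
#'   \code{converged}, \code{n}, \code{saddle}.
#' @export
em_haplotype_freqs <- function(counts, tol = 1e-8, max_iter = 1000L) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3L, 3L)))
  n <- sum(counts)
  if (n < 2) stop("need at least 2 pairwise-complete individuals")
  # flatten row-major: n00 n01 n02 n10 n11 n12 n20 n21 n22
  N <- matrix(as.numeric(t(counts)), nrow = 1)
  r <- .em_many(N, tol = tol, max_iter = max_iter)
  if (r[1, "pA"] <= 0 || r[1, "pA"] >= 1 || r[1, "pB"] <= 0 || r[1, "pB"] >= 1)
    stop("LD undefined: a marker is monomorphic in the pairwise-complete subset")
  structure(list(pAB = unname(r[1, "pAB"]), pAb = unname(r[1, "pAb"]),
                 paB = unname(r[1, "paB"]), pab = unname(r[1, "pab"]),
                 pA = unname(r[1, "pA"]), pB = unname(r[1, "pB"]),
                 iter = as.integer(r[1, "iter"]),
                 converged = unname(r[1, "converged"]) == 1,
                 n = as.integer(r[1, "n"]),
                 saddle = unname(r[1, "saddle"]) == 1),
            class = "hap_freqs")
}

# Vectorised D, Dmax, |D'|, r2 from haplotype/marginal frequencies.
.ld_stats <- function(pAB, pA, pB) {
  pa <- 1 - pA; pb <- 1 - pB
  D <- pAB - pA * pB
  dmax_pos <- pmin(pA * pb, pa * pB)
  dmax_neg <- pmin(pA * pB, pa * pb)
  dmax <- ifelse(D > 0, dmax_pos, dmax_neg)
  dprime <- ifelse(D == 0, 0, abs(D) / dmax)
  dprime <- pmin(dprime, 1)  # guard rounding at the boundary
  r2 <- D^2 / (pA * pa * pB * pb)
  r2 <- pmin(r2, 1)
  cbind(D = D, Dmax = dmax, Dprime = dprime, r2 = r2)
}

#' LD statistics from haplotype frequencies
#'
#' Computes the disequilibrium coefficient \eqn{D = \rho_{AB} - \rho_A\rho_B},
#' its frequency-constrained maximum \eqn{D_{max}} (\eqn{\min(\rho_A\rho_b,
#' \rho_a\rho_B)} for positive D, \eqn{\min(\rho_A\rho_B, \rho_a\rho_b)} in
#' magnitude for negative D), the normalized \eqn{|D'| = |D|/D_{max}} (0 when
#' D = 0) and \eqn{r^2 = D^2/(\rho_A\rho_a\rho_B\rho_b)}.
#'
#' @param freqs a \code{hap_freqs} object, or a list with \code{pAB},
#'   \code{pA}, \code{pB}.
#' @return list of class \code{ld_estimate}: \code{D}, \code{Dmax},
#'   \code{Dprime} (the absolute value), \code{r2}, plus the input
#'   frequencies.
#' @export
ld_from_freqs <- function(freqs) {
  pA <- freqs$pA; pB <- freqs$pB; pAB <- freqs$pAB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("LD undefined: marginal frequency at 0 or 1")
  s <- .ld_stats(pAB, pA, pB)
  structure(list(D = unname(s[1, "D"]), Dmax = unname(s[1, "Dmax"]),
                 Dprime = unname(s[1, "Dprime"]), r2 = unname(s[1, "r2"]),
                 pAB = pAB, pA = pA, pB = pB,
                 saddle = isTRUE(freqs$saddle)),
            class = "ld_estimate")
}

# Genotype log-likelihood over a grid of pAB values with margins fixed.
# counts: 3x3; returns list(pab_grid, loglik, dprime).
.profile_loglik <- function(counts, n_grid = 1001L) {
  n <- sum(counts)
  twoN <- 2 * n
  cn <- as.numeric(t(counts))  # n00 n01 n02 n10 n11 n12 n20 n21 n22
  pA <- (2 * sum(counts[3, ]) + sum(counts[2, ])) / twoN
  pB <- (2 * sum(counts[, 3]) + sum(counts[, 2])) / twoN
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  g <- seq(lo, hi, length.out = n_grid)
  pAB <- g
  pAb <- pA - pAB
  paB <- pB - pAB
  pab <- 1 - pA - pB + pAB
  # genotype probabilities under random union of haplotypes,
  # ordered to match cn: n00 n01 n02 n10 n11 n12 n20 n21 n22
  probs <- cbind(
    pab^2,                       # (0,0)
    2 * paB * pab,               # (0,1)
    paB^2,                       # (0,2)
    2 * pAb * pab,               # (1,0)
    2 * (pAB * pab + pAb * paB), # (1,1)
    2 * pAB * paB,               # (1,2)
    pAb^2,                       # (2,0)
    2 * pAB * pAb,               # (2,1)
    pAB^2)                       # (2,2)
  ll <- as.vector(log(pmax(probs, 1e-300)) %*% cn)
  s <- .ld_stats(pAB, rep(pA, n_grid), rep(pB, n_grid))
  list(pAB = pAB, pA = pA, pB = pB, loglik = ll, dprime = s[, "Dprime"])
}

#' Likelihood-based confidence interval for |D'|
#'
#' Profiles the multinomial genotype log-likelihood over the admissible
#' range of \eqn{\rho_{AB}} (margins fixed at their sample values),
#' converts each grid point to \eqn{|D'|}, and returns the range of
#' \eqn{|D'|} values whose log-likelihood stays within
#' \eqn{\chi^2_1(level)/2} of the maximum — the profile likelihood-ratio
#' interval. This is the interval used by the Gabriel-style block
#' criterion.
#'
#' @param counts 3x3 matrix from \code{\link{two_locus_counts}}.
#' @param level interval level (default 0.90).
#' @param n_grid grid resolution (default 1001).
#' @return named numeric \code{c(lower, upper)} on the |D'| scale.
#' @export
dprime_confidence_interval <- function(counts, level = 0.90,
                                       n_grid = 1001L) {
  counts <- as.matrix(counts)
  if (sum(counts) < 2) stop("need at least 2 pairwise-complete individuals")
  pr <- .profile_loglik(counts, n_grid = n_grid)
  if (pr$pA <= 0 || pr$pA >= 1 || pr$pB <= 0 || pr$pB >= 1)
    stop("LD undefined: a marker is monomorphic in the pairwise-complete subset")
  cut <- stats::qchisq(level, df = 1) / 2
  keep <- pr$loglik >= max(pr$loglik) - cut
  c(lower = min(pr$dprime[keep]), upper = max(pr$dprime[keep]))
}

# Build k x 9 two-locus count matrix for index pairs (i, j) of a dosage
# matrix via indicator cross-products; returns columns in .em_many order.
.pair_counts <- function(geno, i_idx, j_idx) {
  I0 <- (!is.na(geno) & geno == 0L) + 0
  I1 <- (!is.na(geno) & geno == 1L) + 0
  I2 <- (!is.na(geno) & geno == 2L) + 0
  ind <- list(I0, I1, I2)
  out <- matrix(0, length(i_idx), 9L)
  col <- 0L
  for (a in 1:3) for (b in 1:3) {
    col <- col + 1L
    cp <- crossprod(ind[[a]], ind[[b]])  # m x m: counts (dose1=a-1, dose2=b-1)
    out[, col] <- cp[cbind(i_idx, j_idx)]
  }
  out
}

#' Pairwise LD estimates over a genotype matrix
#'
#' Computes EM-based LD for every within-chromosome marker pair
#' (\code{mode = "all"}) or for consecutive map-order pairs
#' (\code{mode = "adjacent"}). Pairs for which LD is undefined (a marker
#' monomorphic within the pairwise-complete subset, or fewer than
#' \code{min_n} complete individuals) are skipped and counted.
#'
#' @param genotypes a \code{geno_matrix} (normally after QC).
#' @param mode \code{"adjacent"} or \code{"all"}.
#' @param tol,max_iter EM controls, see \code{\link{em_haplotype_freqs}}.
#' @param min_n minimum pairwise-complete individuals (default 2).
#' @return data.frame of class \code{ld_estimates} with one row per
#'   estimable pair: \code{chrom}, \code{id1}, \code{id2}, \code{bp1},
#'   \code{bp2}, \code{dist_bp}, \code{D}, \code{Dprime}, \code{r2},
#'   \code{n}, \code{pAB}, \code{pA}, \code{pB}, \code{converged},
#'   \code{saddle}. The skipped-pair count is in
#'   \code{attr(x, "n_skipped")}.
#' @export
pairwise_ld <- function(genotypes, mode = c("adjacent", "all"),
                        tol = 1e-8, max_iter = 1000L, min_n = 2L) {
  mode <- match.arg(mode)
  g <- genotypes
  chroms <- unique(g$map$chrom)
  res <- vector("list", length(chroms))
  n_skipped <- 0L
  for (ci in seq_along(chroms)) {
    idx <- which(g$map$chrom == chroms[ci])
    m <- length(idx)
    if (m < 2L) next
    if (mode == "adjacent") {
      i_loc <- seq_len(m - 1L); j_loc <- i_loc + 1L
    } else {
      cmb <- utils::combn(m, 2L)
      i_loc <- cmb[1, ]; j_loc <- cmb[2, ]
    }
    sub <- g$geno[, idx, drop = FALSE]
    N <- .pair_counts(sub, i_loc, j_loc)
    r <- .em_many(N, tol = tol, max_iter = max_iter)
    ok <- r[, "n"] >= min_n & is.finite(r[, "pA"]) & is.finite(r[, "pB"]) &
      r[, "pA"] > 0 & r[, "pA"] < 1 & r[, "pB"] > 0 & r[, "pB"] < 1
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    r <- r[ok, , drop = FALSE]
    i_g <- idx[i_loc[ok]]; j_g <- idx[j_loc[ok]]
    s <- .ld_stats(r[, "pAB"], r[, "pA"], r[, "pB"])
    res[[ci]] <- data.frame(
      chrom = chroms[ci],
      id1 = g$map$id[i_g], id2 = g$map$id[j_g],
      bp1 = g$map$pos[i_g], bp2 = g$map$pos[j_g],
      dist_bp = g$map$pos[j_g] - g$map$pos[i_g],
      D = s[, "D"], Dprime = s[, "Dprime"], r2 = s[, "r2"],
      n = as.integer(r[, "n"]),
      pAB = r[, "pAB"], pA = r[, "pA"], pB = r[, "pB"],
      converged = r[, "converged"] == 1,
      saddle = r[, "saddle"] == 1,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(
    chrom = character(0), id1 = character(0), id2 = character(0),
    bp1 = integer(0), bp2 = integer(0), dist_bp = integer(0),
    D = numeric(0), Dprime = numeric(0), r2 = numeric(0), n = integer(0),
    pAB = numeric(0), pA = numeric(0), pB = numeric(0),
    converged = logical(0), saddle = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ld_estimates", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_samples") <- nrow(g$geno)
  out
}

#' Write LD estimates as TSV
#'
#' @param estimates output of \code{\link{pairwise_ld}}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_ld_tsv <- function(estimates, path) {
  cols <- c("chrom", "id1", "id2", "bp1", "bp2", "dist_bp",
            "D", "Dprime", "r2", "n")
  utils::write.table(format(as.data.frame(estimates)[, cols], digits = 10,
                            trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
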