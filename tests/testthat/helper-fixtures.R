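# Shared fixture builders and independent oracles for the test suite.

# small hand-built geno_matrix; every marker's first individual carries
# allele A, so dosage orientation survives a .ped round-trip
make_tiny_geno <- function() {
  geno <- rbind(c(2L, 1L, 1L, 2L),
                c(1L, 1L, 2L, NA),
                c(0L, 2L, 0L, 0L))
  map <- data.frame(chrom = c("1", "1", "1", "2"),
                    id = paste0("m", 1:4),
                    pos = c(100L, 200L, 300L, 150L))
  geno_matrix(geno, map, ids = c("a", "b", "c"))
}

# 3x3 count table from named cell values, e.g. tab3(n22 = 2, n00 = 2)
tab3 <- function(...) {
  v <- list(...)
  m <- matrix(0L, 3, 3, dimnames = list(d1 = 0:2, d2 = 0:2))
  for (nm in names(v)) {
    i <- as.integer(substr(nm, 2, 2)); j <- as.integer(substr(nm, 3, 3))
    m[i + 1L, j + 1L] <- as.integer(v[[nm]])
  }
  m
}

# independent multinomial genotype log-likelihood of a 3x3 table at
# haplotype frequency pAB (margins from the table); used as the EM oracle
oracle_loglik <- function(counts, pAB) {
  n <- sum(counts)
  pA <- (2 * sum(counts[3, ]) + sum(counts[2, ])) / (2 * n)
  pB <- (2 * sum(counts[, 3]) + sum(counts[, 2])) / (2 * n)
  pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
  probs <- cbind(pab^2, 2 * paB * pab, paB^2,
                 2 * pAb * pab, 2 * (pAB * pab + pAb * paB), 2 * pAB * paB,
                 pAb^2, 2 * pAB * pAb, pAB^2)
  cn <- as.numeric(t(counts))
  as.vector(log(pmax(probs, 1e-300)) %*% cn)
}

# grid-search oracle: pAB maximizing the genotype likelihood
oracle_grid_max <- function(counts, step = 1e-4) {
  n <- sum(counts)
  pA <- (2 * sum(counts[3, ]) + sum(counts[2, ])) / (2 * n)
  pB <- (2 * sum(counts[, 3]) + sum(counts[, 2])) / (2 * n)
  g <- seq(max(0, pA + pB - 1), min(pA, pB), by = step)
  ll <- oracle_loglik(counts, g)
  list(pAB = g[which.max(ll)], loglik = max(ll))
}

# all 3x3 tables (as a k x 9 matrix, row-major cell order) with sum <= nmax
enumerate_tables <- function(nmax) {
  rows <- list()
  rec <- function(prefix, remaining, cells_left) {
    if (cells_left == 1L) {
      for (v in 0:remaining) rows[[length(rows) + 1L]] <<- c(prefix, v)
      return(invisible())
    }
    for (v in 0:remaining) rec(c(prefix, v), remaining - v, cells_left - 1L)
  }
  rec(integer(0), nmax, 9L)
  do.call(rbind, rows)
}

# genotypes built from explicit phase-known haplotype pairs:
# h1, h2 are n x m 0/1 matrices
geno_from_haplotypes <- function(h1, h2, spacing_bp = 1e5) {
  m <- ncol(h1)
  map <- data.frame(chrom = "1", id = paste0("s", seq_len(m)),
                    pos = as.integer(spacing_bp * seq_len(m)))
  geno_matrix(h1 + h2, map)
}
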