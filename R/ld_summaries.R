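#' Per-chromosome LD summary
#'
#' Unweighted arithmetic mean and sample SD (n-1) of r-squared and |D'| per
#' chromosome, with the number of pairs and the mean intermarker distance,
#' plus a genome-wide row. The genome-wide mean is the pooled mean over all
#' pairs; the unweighted average of the chromosome means is reported
#' alongside it.
#'
#' @param estimates an \code{ld_estimates} data.frame.
#' @return data.frame with one row per chromosome plus a \code{"genome"}
#'   row: \code{chrom}, \code{n_pairs}, \code{mean_dist_mb},
#'   \code{mean_r2}, \code{sd_r2}, \code{mean_dprime}, \code{sd_dprime},
#'   and for the genome row \code{mean_r2_chrom_avg},
#'   \code{mean_dprime_chrom_avg} (NA elsewhere).
#' @export
summarize_by_chromosome <- function(estimates) {
  e <- as.data.frame(estimates)
  if (nrow(e) == 0L)
    return(data.frame(chrom = character(0), n_pairs = integer(0),
                      mean_dist_mb = numeric(0), mean_r2 = numeric(0),
                      sd_r2 = numeric(0), mean_dprime = numeric(0),
                      sd_dprime = numeric(0),
                      mean_r2_chrom_avg = numeric(0),
                      mean_dprime_chrom_avg = numeric(0),
                      stringsAsFactors = FALSE))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  per <- lapply(split(e, factor(e$chrom, levels = unique(e$chrom))),
                function(d) data.frame(
    chrom = d$chrom[1], n_pairs = nrow(d),
    mean_dist_mb = mean(d$dist_bp) / 1e6,
    mean_r2 = mean(d$r2), sd_r2 = sd0(d$r2),
    mean_dprime = mean(d$Dprime), sd_dprime = sd0(d$Dprime),
    mean_r2_chrom_avg = NA_real_, mean_dprime_chrom_avg = NA_real_,
    stringsAsFactors = FALSE))
  per <- do.call(rbind, per)
  genome <- data.frame(
    chrom = "genome", n_pairs = nrow(e),
    mean_dist_mb = mean(e$dist_bp) / 1e6,
    mean_r2 = mean(e$r2), sd_r2 = sd0(e$r2),
    mean_dprime = mean(e$Dprime), sd_dprime = sd0(e$Dprime),
    mean_r2_chrom_avg = mean(per$mean_r2),
    mean_dprime_chrom_avg = mean(per$mean_dprime),
    stringsAsFactors = FALSE)
  out <- rbind(per, genome)
  rownames(out) <- NULL
  out
}

#' Distance-binned LD decay table
#'
#' Assigns each pair to a distance bin (left-closed, right-open, in Mb) and
#' reports per-bin pair counts and mean r-squared and |D'|. Pairs beyond the
#' last edge are counted as overflow.
#'
#' @param estimates an \code{ld_estimates} data.frame.
#' @param edges_mb strictly increasing bin edges in Mb.
#' @return data.frame with \code{bin_lo_mb}, \code{bin_hi_mb},
#'   \code{n_pairs}, \code{mean_dist_mb}, \code{mean_r2},
#'   \code{mean_dprime}; overflow and underflow pair counts are attached as
#'   attributes \code{n_overflow} / \code{n_underflow}.
#' @export
bin_by_distance <- function(estimates, edges_mb) {
  if (is.unsorted(edges_mb, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  e <- as.data.frame(estimates)
  d_mb <- e$dist_bp / 1e6
  k <- length(edges_mb) - 1L
  bin <- findInterval(d_mb, edges_mb, rightmost.closed = FALSE)
  n_underflow <- sum(bin == 0L)
  n_overflow <- sum(bin > k)
  out <- data.frame(bin_lo_mb = edges_mb[seq_len(k)],
                    bin_hi_mb = edges_mb[-1],
                    n_pairs = 0L, mean_dist_mb = NA_real_,
                    mean_r2 = NA_real_, mean_dprime = NA_real_)
  for (b in seq_len(k)) {
    sel <- bin == b
    out$n_pairs[b] <- sum(sel)
    if (any(sel)) {
      out$mean_dist_mb[b] <- mean(d_mb[sel])
      out$mean_r2[b] <- mean(e$r2[sel])
      out$mean_dprime[b] <- mean(e$Dprime[sel])
    }
  }
  attr(out, "n_overflow") <- n_overflow
  attr(out, "n_underflow") <- n_underflow
  out
}

#' LD category table (low / medium / high r-squared)
#'
#' Classifies pairs as low (\eqn{r^2 \le 0.16}), medium
#' (\eqn{0.16 < r^2 < 0.70}) or high (\eqn{r^2 \ge 0.70}) LD, and reports
#' per chromosome and category the mean r-squared, mean intermarker
#' distance (Mb) and the percentage of that chromosome's pairs.
#'
#' @param estimates an \code{ld_estimates} data.frame.
#' @param low_max upper bound of the low category (default 0.16, inclusive).
#' @param high_min lower bound of the high category (default 0.70,
#'   inclusive).
#' @return data.frame: \code{chrom}, \code{category}, \code{n_pairs},
#'   \code{mean_r2}, \code{mean_dist_mb}, \code{freq_pct}. Percentages sum
#'   to 100 within each chromosome.
#' @export
categorize <- function(estimates, low_max = 0.16, high_min = 0.70) {
  e <- as.data.frame(estimates)
  cat_of <- function(r2) ifelse(r2 >= high_min, "high",
                          ifelse(r2 <= low_max, "low", "medium"))
  e$category <- factor(cat_of(e$r2), levels = c("high", "medium", "low"))
  res <- list()
  for (ch in unique(e$chrom)) {
    d <- e[e$chrom == ch, ]
    for (cat in levels(e$category)) {
      dd <- d[d$category == cat, ]
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, category = cat, n_pairs = nrow(dd),
        mean_r2 = if (nrow(dd)) mean(dd$r2) else NA_real_,
        mean_dist_mb = if (nrow(dd)) mean(dd$dist_bp) / 1e6 else NA_real_,
        freq_pct = 100 * nrow(dd) / nrow(d),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correlation between the r-squared and |D'| series
#'
#' Product-moment correlation over paired (r-squared, |D'|) values of an LD
#' estimate set. With zero variance in either series the correlation is
#' undefined and \code{NA} is returned with a warning.
#'
#' @param estimates an \code{ld_estimates} data.frame (>= 2 rows).
#' @return numeric scalar.
#' @export
correlate_metrics <- function(estimates) {
  e <- as.data.frame(estimates)
  if (nrow(e) < 2L) stop("need at least 2 LD estimates")
  if (stats::sd(e$r2) == 0 || stats::sd(e$Dprime) == 0) {
    warning("zero variance in r2 or |D'|; correlation undefined")
    return(NA_real_)
  }
  stats::cor(e$r2, e$Dprime)
}
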