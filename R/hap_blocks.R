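#' Haplotype-block configuration
#'
#' Thresholds for the confidence-interval block criterion: a marker pair is
#' in "strong LD" when its |D'| CI lower bound reaches
#' \code{strong_lower} and the upper bound reaches \code{strong_upper}; it
#' shows "strong recombination" when the upper bound stays below
#' \code{recomb_upper}; all other pairs are uninformative. A candidate
#' marker interval is a block when it has at least one informative pair and
#' the strong-LD fraction among informative pairs reaches
#' \code{strong_fraction}.
#'
#' @param ci_level |D'| confidence-interval mass (default 0.90).
#' @param strong_lower strong-LD lower-bound threshold (default 0.70).
#' @param strong_upper strong-LD upper-bound threshold (default 0.98).
#' @param recomb_upper strong-recombination upper-bound threshold
#'   (default 0.90).
#' @param strong_fraction required strong-LD fraction among informative
#'   pairs (default 0.95).
#' @param max_span_bp maximum block span in bp (default 500000).
#' @param min_maf markers below this MAF are excluded from block search
#'   (default 0.05).
#' @return list of class \code{block_config}.
#' @export
block_config <- function(ci_level = 0.90, strong_lower = 0.70,
                         strong_upper = 0.98, recomb_upper = 0.90,
                         strong_fraction = 0.95, max_span_bp = 500000L,
                         min_maf = 0.05) {
  b <- c(ci_level, strong_lower, strong_upper, recomb_upper,
         strong_fraction, min_maf)
  if (any(b < 0 | b > 1)) stop("bounds must lie in [0, 1]")
  structure(list(ci_level = ci_level, strong_lower = strong_lower,
                 strong_upper = strong_upper, recomb_upper = recomb_upper,
                 strong_fraction = strong_fraction,
                 max_span_bp = as.integer(max_span_bp), min_maf = min_maf),
            class = "block_config")
}

# classify all within-span pairs of one chromosome: returns data.frame
# (i, j, class) with class in {"strong","recomb","uninf"}; i, j are local
# marker indices.
.classify_pairs <- function(geno, pos, config) {
  m <- ncol(geno)
  pairs <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (pos[j] - pos[i] > config$max_span_bp) break
      cnt <- two_locus_counts(geno[, i], geno[, j])
      cls <- "uninf"
      n <- sum(cnt)
      pA <- (2 * sum(cnt[3, ]) + sum(cnt[2, ])) / (2 * n)
      pB <- (2 * sum(cnt[, 3]) + sum(cnt[, 2])) / (2 * n)
      if (n >= 2 && pA > 0 && pA < 1 && pB > 0 && pB < 1) {
        ci <- dprime_confidence_interval(cnt, level = config$ci_level)
        if (ci["lower"] >= config$strong_lower &&
            ci["upper"] >= config$strong_upper) cls <- "strong"
        else if (ci["upper"] < config$recomb_upper) cls <- "recomb"
      }
      pairs[[length(pairs) + 1L]] <- c(i, j, match(cls, c("strong", "recomb",
                                                          "uninf")))
    }
  }
  if (!length(pairs))
    return(data.frame(i = integer(0), j = integer(0), class = integer(0)))
  p <- do.call(rbind, pairs)
  data.frame(i = p[, 1], j = p[, 2], class = p[, 3])
}

#' Gabriel-style haplotype blocks
#'
#' Partitions each chromosome into haplotype blocks from |D'| confidence
#' intervals: every within-span marker pair is classified as strong LD,
#' strong recombination, or uninformative (see \code{\link{block_config}});
#' a candidate interval of two or more markers is a block when all its
#' pairs lie within the span limit, at least one pair is informative and
#' the strong-LD fraction among informative pairs meets the threshold.
#' Overlaps are resolved greedily: longest span first, ties to the smaller
#' start position.
#'
#' @param genotypes a \code{geno_matrix} (normally after QC).
#' @param config a \code{block_config}.
#' @return data.frame of class \code{hap_blocks}: \code{chrom},
#'   \code{first_id}, \code{last_id}, \code{first_idx}, \code{last_idx}
#'   (indices into the chromosome's retained-marker list), \code{start_bp},
#'   \code{end_bp}, \code{n_markers}, \code{span_bp},
#'   \code{mean_spacing_mb}, \code{strong_fraction}.
#' @export
gabriel_blocks <- function(genotypes, config = block_config()) {
  g <- genotypes
  st <- allele_stats(g)
  blocks <- list()
  for (ch in unique(g$map$chrom)) {
    sel <- which(g$map$chrom == ch & !is.na(st$maf) & st$maf >= config$min_maf)
    if (length(sel) < 2L) next
    geno <- g$geno[, sel, drop = FALSE]
    pos <- g$map$pos[sel]
    ids <- g$map$id[sel]
    cls <- .classify_pairs(geno, pos, config)
    if (!nrow(cls)) next
    key <- paste(cls$i, cls$j)
    class_of <- cls$class
    names(class_of) <- key
    m <- length(sel)
    cand <- list()
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (pos[j] - pos[i] > config$max_span_bp) break
        kk <- outer(i:(j - 1L), (i + 1L):j, function(a, b) paste(a, b))
        kk <- kk[upper.tri(matrix(0, j - i, j - i), diag = TRUE)]
        cc <- class_of[kk]
        if (any(is.na(cc))) next   # some pair exceeded span: not a candidate
        n_strong <- sum(cc == 1L)
        n_inf <- sum(cc != 3L)
        if (n_inf >= 1L && n_strong / n_inf >= config$strong_fraction) {
          cand[[length(cand) + 1L]] <-
            c(i = i, j = j, span = pos[j] - pos[i],
              frac = n_strong / n_inf)
        }
      }
    }
    if (!length(cand)) next
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, "span"], cm[, "i"]), , drop = FALSE]
    taken <- rep(FALSE, m)
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; j <- cm[r, "j"]
      if (any(taken[i:j])) next
      taken[i:j] <- TRUE
      spac <- diff(pos[i:j])
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = ch, first_id = ids[i], last_id = ids[j],
        first_idx = i, last_idx = j,
        start_bp = pos[i], end_bp = pos[j],
        n_markers = j - i + 1L, span_bp = pos[j] - pos[i],
        mean_spacing_mb = mean(spac) / 1e6,
        strong_fraction = cm[r, "frac"],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else data.frame(
    chrom = character(0), first_id = character(0), last_id = character(0),
    first_idx = integer(0), last_idx = integer(0),
    start_bp = integer(0), end_bp = integer(0), n_markers = integer(0),
    span_bp = integer(0), mean_spacing_mb = numeric(0),
    strong_fraction = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hap_blocks", "data.frame")
  out
}

#' Haplotype-block statistics
#'
#' Per-chromosome block counts, the block-size frequency histogram keyed by
#' marker count, and the genome-wide mean and SD of within-block adjacent
#' intermarker distances.
#'
#' @param blocks output of \code{\link{gabriel_blocks}}.
#' @param genotypes optional \code{geno_matrix}; when supplied, spacing
#'   statistics use the exact within-block adjacent distances recomputed
#'   from the map, otherwise each block's stored mean spacing is averaged
#'   weighted by its spacing count.
#' @return list: \code{per_chromosome} (chrom, n_blocks, n_markers_total),
#'   \code{size_histogram} (n_markers, count), \code{mean_spacing_mb},
#'   \code{sd_spacing_mb}, \code{n_spacings}.
#' @export
block_stats <- function(blocks, genotypes = NULL) {
  b <- as.data.frame(blocks)
  if (nrow(b) == 0L)
    return(list(per_chromosome = data.frame(chrom = character(0),
                                            n_blocks = integer(0),
                                            n_markers_total = integer(0)),
                size_histogram = data.frame(n_markers = integer(0),
                                            count = integer(0)),
                mean_spacing_mb = NA_real_, sd_spacing_mb = NA_real_,
                n_spacings = 0L))
  per <- do.call(rbind, lapply(unique(b$chrom), function(ch) {
    d <- b[b$chrom == ch, ]
    data.frame(chrom = ch, n_blocks = nrow(d),
               n_markers_total = sum(d$n_markers), stringsAsFactors = FALSE)
  }))
  sizes <- sort(unique(b$n_markers))
  hist <- data.frame(n_markers = sizes,
                     count = vapply(sizes, function(s)
                       sum(b$n_markers == s), integer(1)))
  spacings <- numeric(0)
  if (!is.null(genotypes)) {
    for (r in seq_len(nrow(b))) {
      sel <- genotypes$map$chrom == b$chrom[r] &
        genotypes$map$pos >= b$start_bp[r] & genotypes$map$pos <= b$end_bp[r]
      spacings <- c(spacings, diff(genotypes$map$pos[sel]) / 1e6)
    }
  } else {
    # reconstruct from stored means, weighted by spacing count
    spacings <- rep(b$mean_spacing_mb, b$n_markers - 1L)
  }
  list(per_chromosome = per, size_histogram = hist,
       mean_spacing_mb = mean(spacings),
       sd_spacing_mb = if (length(spacings) > 1L) stats::sd(spacings) else 0,
       n_spacings = length(spacings))
}

#' Recommended marker count from block spacing
#'
#' The marker density needed to tag the genome at the within-block spacing:
#' the genome length divided by the mean intermarker distance inside
#' haplotype blocks, rounded to the nearest integer.
#'
#' @param genome_size_mb total genome length in Mb (> 0).
#' @param mean_block_spacing_mb mean within-block intermarker distance in
#'   Mb (> 0).
#' @return integer marker count.
#' @export
recommended_marker_count <- function(genome_size_mb, mean_block_spacing_mb) {
  if (genome_size_mb <= 0) stop("genome size must be positive")
  if (mean_block_spacing_mb <= 0) stop("block spacing must be positive")
  as.integer(round(genome_size_mb / mean_block_spacing_mb))
}

#' Write block tables
#'
#' @param blocks output of \code{\link{gabriel_blocks}}.
#' @param stats output of \code{\link{block_stats}}.
#' @param bed_path BED-like TSV (chrom, start_bp, end_bp, n_markers).
#' @param hist_path size-histogram TSV.
#' @return Invisibly, the paths written.
#' @export
write_block_tables <- function(blocks, stats, bed_path, hist_path) {
  bed <- as.data.frame(blocks)[, c("chrom", "start_bp", "end_bp",
                                   "n_markers")]
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(stats$size_histogram, hist_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(bed_path, hist_path))
}
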