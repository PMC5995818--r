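#' Genome coverage of a marker map
#'
#' Span is the per-chromosome distance between the outermost markers,
#' summed over chromosomes, in Mb; the headline percentage is the span (or
#' a supplied span, e.g. a published figure) over the total genome length,
#' rounded to the nearest integer.
#'
#' @param markermap marker map data.frame (chrom, id, pos); may be
#'   \code{NULL} when \code{span_mb} is supplied directly.
#' @param genome_length_mb total genome length in Mb (> 0); the ovine
#'   reference length 2615.52 Mb is the package default elsewhere.
#' @param span_mb optional externally supplied span in Mb, overriding the
#'   map-derived span.
#' @return list: \code{span_mb}, \code{percent} (exact) and
#'   \code{percent_rounded}.
#' @export
genome_coverage <- function(markermap, genome_length_mb, span_mb = NULL) {
  if (genome_length_mb <= 0) stop("genome length must be positive")
  if (is.null(span_mb)) {
    if (is.null(markermap) || nrow(markermap) == 0L)
      stop("empty marker map")
    span_mb <- sum(vapply(split(markermap$pos, markermap$chrom),
                          function(p) diff(range(p)), numeric(1))) / 1e6
  }
  pct <- 100 * span_mb / genome_length_mb
  list(span_mb = span_mb, percent = pct,
       percent_rounded = as.integer(round(pct)))
}

#' Run the full LD-characterization analysis
#'
#' Executes the analysis stages in a fixed order — QC, adjacent and
#' all-pairwise LD, per-chromosome and distance-binned summaries, LD
#' categories, metric correlation, inbreeding, the VanRaden G matrix and
#' its relationship summary, the Sved-equation Ne trajectory, Gabriel
#' haplotype blocks with statistics, the marker-density recommendation and
#' genome coverage — and returns everything as one report bundle. With an
#' output directory the bundle is also written as TSV tables plus a YAML
#' run manifest; identical inputs and configuration produce byte-identical
#' tables.
#'
#' @param genotypes a \code{geno_matrix}, or a list of input paths
#'   (\code{list(ped =, map =)} or \code{list(vcf =)}).
#' @param qc a \code{qc_config}.
#' @param ne a \code{ne_config}.
#' @param blocks a \code{block_config}.
#' @param genome_length_mb total genome length in Mb (default 2615.52, the
#'   ovine reference).
#' @param out_dir optional output directory for the TSV tables and
#'   manifest.
#' @param decay_edges_mb bin edges for the decay tables (default 0.1-Mb
#'   bins to 10 Mb).
#' @return list of class \code{report_bundle}; see the vignette for the
#'   table inventory.
#' @export
run_full_analysis <- function(genotypes,
                              qc = qc_config(),
                              ne = ne_config(),
                              blocks = block_config(),
                              genome_length_mb = 2615.52,
                              out_dir = NULL,
                              decay_edges_mb = seq(0, 10, by = 0.1)) {
  input_checksums <- NULL
  if (!inherits(genotypes, "geno_matrix")) {
    paths <- unlist(genotypes)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input path(s) not found: ", paste(missing, collapse = ", "))
    input_checksums <- as.list(tools::md5sum(paths))
    genotypes <- if (!is.null(genotypes$vcf)) read_vcf(genotypes$vcf)
                 else read_ped_map(genotypes$ped, genotypes$map)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  qcres <- stage("qc", run_qc(genotypes, qc))
  g <- qcres$genotypes
  ld_adj <- stage("ld_adjacent", pairwise_ld(g, mode = "adjacent"))
  ld_all <- stage("ld_all", pairwise_ld(g, mode = "all"))
  summ_adj <- stage("summaries", summarize_by_chromosome(ld_adj))
  summ_all <- stage("summaries", summarize_by_chromosome(ld_all))
  decay <- stage("summaries", bin_by_distance(ld_all, decay_edges_mb))
  categories <- stage("summaries", categorize(ld_all))
  cor_adj <- stage("summaries", correlate_metrics(ld_adj))
  cor_all <- stage("summaries", correlate_metrics(ld_all))
  inb <- stage("inbreeding", inbreeding(g))
  G <- stage("grm", vanraden_grm(g))
  g_summary <- stage("grm", relationship_summary(G))
  ne_res <- stage("ne", ne_trajectory(ld_all, ne))
  blk <- stage("blocks", gabriel_blocks(g, blocks))
  blk_stats <- stage("blocks", block_stats(blk, g))
  density <- if (nrow(blk) && is.finite(blk_stats$mean_spacing_mb) &&
                 blk_stats$mean_spacing_mb > 0)
    stage("density", recommended_marker_count(genome_length_mb,
                                              blk_stats$mean_spacing_mb))
  else NA_integer_
  coverage <- stage("coverage", genome_coverage(g$map, genome_length_mb))
  bundle <- structure(list(
    qc_report = qcres$report,
    ld_adjacent = ld_adj, ld_all = ld_all,
    chrom_summary_adjacent = summ_adj, chrom_summary_all = summ_all,
    decay = decay, categories = categories,
    metric_correlation = c(adjacent = cor_adj, all = cor_all),
    inbreeding = inb, G = G, g_summary = g_summary,
    ne = ne_res, blocks = blk, block_stats = blk_stats,
    recommended_markers = density, coverage = coverage,
    n_samples = nrow(g$geno), n_markers = ncol(g$geno),
    config = list(qc = qc, ne = ne, blocks = blocks,
                  genome_length_mb = genome_length_mb),
    input_checksums = input_checksums),
    class = "report_bundle")
  if (!is.null(out_dir)) write_report_tables(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("LD report bundle:\n")
  cat(sprintf("  %d samples x %d markers after QC\n",
              x$n_samples, x$n_markers))
  cat(sprintf("  adjacent pairs: %d (mean r2 %.4f, mean |D'| %.4f)\n",
              nrow(x$ld_adjacent), mean(x$ld_adjacent$r2),
              mean(x$ld_adjacent$Dprime)))
  cat(sprintf("  all pairs: %d (mean r2 %.4f)\n",
              nrow(x$ld_all), mean(x$ld_all$r2)))
  cat(sprintf("  mean F: %.4f; recent Ne: %.1f; blocks: %d\n",
              x$inbreeding$mean_F, x$ne$recent_Ne, nrow(x$blocks)))
  invisible(x)
}

# format a data.frame deterministically for TSV output
.write_tsv <- function(d, path) {
  num <- vapply(d, is.double, logical(1))
  d[num] <- lapply(d[num], function(x) signif(x, 8))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a report bundle as TSV tables
#'
#' Emits one TSV per reporting surface (QC per-chromosome counts,
#' per-chromosome LD summaries, decay table, category table, inbreeding
#' table, G triplets, Ne trajectory, blocks and block histogram) plus a
#' \code{manifest.yml} with the configuration, package version and input
#' checksums. Output is byte-stable for identical input.
#'
#' @param bundle a \code{report_bundle}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_report_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- character(0)
  f <- function(name) file.path(dir, name)
  .write_tsv(bundle$qc_report$per_chromosome, f("qc_per_chromosome.tsv"))
  .write_tsv(bundle$chrom_summary_adjacent, f("ld_summary_adjacent.tsv"))
  .write_tsv(bundle$chrom_summary_all, f("ld_summary_all.tsv"))
  .write_tsv(bundle$decay, f("ld_decay.tsv"))
  .write_tsv(bundle$categories, f("ld_categories.tsv"))
  write_ld_tsv(bundle$ld_adjacent, f("ld_adjacent.tsv"))
  write_relatedness_tables(bundle$inbreeding, bundle$G,
                           f("inbreeding.tsv"), f("grm_triplets.tsv"))
  .write_tsv(bundle$ne$bins, f("ne_trajectory.tsv"))
  .write_tsv(bundle$ne$per_chromosome, f("ne_per_chromosome.tsv"))
  write_block_tables(bundle$blocks, bundle$block_stats,
                     f("blocks.tsv"), f("block_size_histogram.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ldscape")),
    n_samples = bundle$n_samples,
    n_markers = bundle$n_markers,
    metric_correlation = as.list(bundle$metric_correlation),
    mean_F = bundle$inbreeding$mean_F,
    recent_Ne = bundle$ne$recent_Ne,
    recommended_markers = bundle$recommended_markers,
    coverage = bundle$coverage,
    genome_length_mb = bundle$config$genome_length_mb,
    qc = unclass(bundle$config$qc),
    ne = unclass(bundle$config$ne),
    blocks = unclass(bundle$config$blocks),
    input_checksums = bundle$input_checksums)
  yaml::write_yaml(manifest, f("manifest.yml"))
  invisible(list.files(dir, full.names = TRUE))
}
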