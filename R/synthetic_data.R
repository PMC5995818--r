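#' Simulation configuration
#'
#' Parameters of the forward Wright-Fisher genotype simulator. The defaults
#' emulate the structure of a domestic-sheep SNP panel: 26 autosomes,
#' regular ~0.07 Mb marker spacing, 1 cM per Mb, initial allele frequencies
#' uniform on [0.2, 0.5] (mean MAF 0.35), and a diploid population of 100
#' (matching a recent effective size near 100) sampled in full. Marker and
#' chromosome counts are kept moderate so a simulation runs in seconds;
#' scale them up freely.
#'
#' @param N diploid population size.
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers per chromosome.
#' @param spacing_bp regular intermarker spacing in bp (default 70000).
#' @param cM_per_Mb genetic-map scaling (default 1).
#' @param generations generations of random mating (default 100; LD at the
#'   distances analysed equilibrates on the 1/(2c) timescale, tens of
#'   generations, while drift erodes polymorphism on the N timescale, so a
#'   burn-in of about N equilibrates LD without fixing most markers).
#' @param maf_range initial allele-frequency range, uniform (default
#'   c(0.2, 0.5)).
#' @param sample_size diploids sampled from the final generation (default
#'   \code{N}, capped at \code{N}).
#' @param seed RNG seed; the generator algorithm is fixed (Mersenne-Twister
#'   as seeded by \code{set.seed}) so seeds are portable.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(N = 100L, n_chromosomes = 26L,
                       markers_per_chromosome = 150L,
                       spacing_bp = 70000L, cM_per_Mb = 1.0,
                       generations = 100L,
                       maf_range = c(0.2, 0.5),
                       sample_size = NULL, seed = 1L) {
  if (is.null(sample_size)) sample_size <- N
  stopifnot(N >= 1, n_chromosomes >= 1, markers_per_chromosome >= 1,
            spacing_bp >= 1, generations >= 0, sample_size >= 1)
  if (sample_size > N) stop("sample_size must not exceed N")
  structure(list(N = as.integer(N),
                 n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 spacing_bp = as.integer(spacing_bp),
                 cM_per_Mb = cM_per_Mb,
                 generations = as.integer(generations),
                 maf_range = maf_range,
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# map for a regular-spacing panel
.sim_map <- function(config) {
  m <- config$markers_per_chromosome
  do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ch)
    data.frame(chrom = as.character(ch),
               id = sprintf("snp_%d_%d", ch, seq_len(m)),
               pos = as.integer(config$spacing_bp * (seq_len(m) - 1L) + 1L),
               stringsAsFactors = FALSE)))
}

# one meiosis for all 2N gametes at once: H is 2N x m (rows 2k-1, 2k are
# individual k), parent picks the diploid parent of each gamete.
# Crossover counts are Poisson in the map length; positions uniform.
.make_gametes <- function(H, parent, marker_morgans) {
  m <- ncol(H)
  L <- marker_morgans[m] - marker_morgans[1]
  n_g <- length(parent)
  first <- H[2L * parent - 1L, , drop = FALSE]
  second <- H[2L * parent, , drop = FALSE]
  start <- sample.int(2L, n_g, replace = TRUE)  # which strand leads
  ncx <- stats::rpois(n_g, L)
  # phase matrix: TRUE -> take `first`, FALSE -> take `second`
  phase <- matrix(start == 1L, n_g, m)
  for (k in which(ncx > 0L)) {
    cx <- sort(stats::runif(ncx[k], marker_morgans[1], marker_morgans[m]))
    flips <- findInterval(marker_morgans, cx)  # crossovers to the left
    ph <- (as.integer(start[k] == 1L) + flips) %% 2L == 1L
    phase[k, ] <- ph
  }
  out <- second
  out[phase] <- first[phase]
  out
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Simulates a constant-size, randomly mating diploid population forward in
#' time with per-chromosome recombination and no mutation, then emits the
#' genotypes of a random final-generation sample. Each generation every
#' offspring draws two parents with replacement and receives one
#' recombinant gamete from each; crossover counts per meiosis are Poisson
#' in the chromosome's genetic length, positions uniform. Fully
#' reproducible per seed.
#'
#' @param config a \code{sim_config}.
#' @return list of class \code{sim_dataset}: \code{genotypes} (a
#'   \code{geno_matrix}), \code{truth} (config, true N per generation, the
#'   sampled individuals' haplotypes per chromosome).
#' @export
simulate_wright_fisher <- function(config = sim_config()) {
  set.seed(config$seed)
  map <- .sim_map(config)
  N <- config$N
  m <- config$markers_per_chromosome
  morg <- physical_to_genetic(map$pos[seq_len(m)] - map$pos[1],
                              config$cM_per_Mb)
  haplos <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    H <- matrix(stats::rbinom(2L * N * m, 1L, rep(p0, each = 2L * N)),
                2L * N, m)
    for (gen in seq_len(config$generations)) {
      # two gametes per offspring, parents independent (selfing allowed,
      # as in the standard Wright-Fisher model)
      par1 <- sample.int(N, N, replace = TRUE)
      par2 <- sample.int(N, N, replace = TRUE)
      g1 <- .make_gametes(H, par1, morg)
      g2 <- .make_gametes(H, par2, morg)
      Hn <- matrix(0L, 2L * N, m)
      Hn[seq(1L, 2L * N, by = 2L), ] <- g1
      Hn[seq(2L, 2L * N, by = 2L), ] <- g2
      H <- Hn
    }
    haplos[[ch]] <- H
  }
  keep <- sort(sample.int(N, config$sample_size))
  geno <- do.call(cbind, lapply(haplos, function(H)
    H[2L * keep - 1L, , drop = FALSE] + H[2L * keep, , drop = FALSE]))
  g <- geno_matrix(geno, map,
                   ids = sprintf("sim_%03d", keep),
                   alleles = data.frame(a1 = rep("A", nrow(map)),
                                        a2 = rep("B", nrow(map)),
                                        stringsAsFactors = FALSE))
  truth <- list(config = config,
                N_per_generation = rep(N, config$generations),
                sampled = keep,
                haplotypes = lapply(haplos, function(H)
                  H[as.vector(rbind(2L * keep - 1L, 2L * keep)), ,
                    drop = FALSE]))
  structure(list(genotypes = g, truth = truth), class = "sim_dataset")
}

#' Pedigreed genotype sample
#'
#' Builds a two-generation sample with known pedigree: unrelated founders
#' drawn at Hardy-Weinberg proportions from uniform allele frequencies,
#' then offspring produced by the matings of \code{family_spec}, each
#' receiving one recombinant gamete per parent (same meiosis model as
#' \code{\link{simulate_wright_fisher}}). Offspring sharing a sire but not
#' a dam are half sibs (expected relationship 0.25); a shared sire and dam
#' gives full sibs (0.5).
#'
#' @param config a \code{sim_config}; \code{N} is the number of founders.
#' @param family_spec data.frame with columns \code{sire}, \code{dam}
#'   (founder indices in 1..N) and \code{n_offspring}.
#' @param include_founders include founders in the emitted sample (default
#'   TRUE).
#' @return list of class \code{sim_dataset} with \code{genotypes} and
#'   \code{truth} (pedigree data.frame id, sire, dam).
#' @export
make_pedigreed_sample <- function(config, family_spec,
                                  include_founders = TRUE) {
  fs <- as.data.frame(family_spec)
  if (!all(c("sire", "dam", "n_offspring") %in% names(fs)))
    stop("family_spec needs columns sire, dam, n_offspring")
  if (any(fs$sire < 1 | fs$sire > config$N |
          fs$dam < 1 | fs$dam > config$N))
    stop("sire/dam indices must be founder indices in 1..N")
  if (any(fs$sire == fs$dam))
    stop("sire and dam must differ")
  set.seed(config$seed)
  map <- .sim_map(config)
  N <- config$N
  m <- config$markers_per_chromosome
  morg <- physical_to_genetic(map$pos[seq_len(m)] - map$pos[1],
                              config$cM_per_Mb)
  n_off <- sum(fs$n_offspring)
  off_sire <- rep(fs$sire, fs$n_offspring)
  off_dam <- rep(fs$dam, fs$n_offspring)
  geno_chunks <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    H <- matrix(stats::rbinom(2L * N * m, 1L, rep(p0, each = 2L * N)),
                2L * N, m)
    g_s <- .make_gametes(H, off_sire, morg)
    g_d <- .make_gametes(H, off_dam, morg)
    off_geno <- g_s + g_d
    founder_geno <- H[seq(1L, 2L * N, by = 2L), , drop = FALSE] +
      H[seq(2L, 2L * N, by = 2L), , drop = FALSE]
    geno_chunks[[ch]] <- if (include_founders)
      rbind(founder_geno, off_geno) else off_geno
  }
  geno <- do.call(cbind, geno_chunks)
  ids <- c(if (include_founders) sprintf("founder_%03d", seq_len(N)),
           sprintf("off_%03d", seq_len(n_off)))
  ped <- data.frame(
    id = ids,
    sire = c(if (include_founders) rep(NA_character_, N),
             sprintf("founder_%03d", off_sire)),
    dam = c(if (include_founders) rep(NA_character_, N),
            sprintf("founder_%03d", off_dam)),
    stringsAsFactors = FALSE)
  g <- geno_matrix(geno, map, ids = ids)
  structure(list(genotypes = g,
                 truth = list(config = config, pedigree = ped,
                              family_spec = fs)),
            class = "sim_dataset")
}

#' Genotypes with a planted complete-LD block
#'
#' Draws each individual's two haplotypes marker by marker: outside the
#' planted range markers are independent with uniform frequencies; inside
#' the range only two complementary haplotypes segregate, so every
#' within-block pair is in complete LD (|D'| = 1).
#'
#' @param config a \code{sim_config} (one chromosome is simulated per
#'   \code{n_chromosomes} as usual; \code{sample_size} individuals are
#'   emitted, drawn directly rather than via forward simulation).
#' @param block_spec list with \code{chrom} (1-based chromosome number),
#'   \code{from}, \code{to} (marker indices on that chromosome, >= 2
#'   markers), and optionally \code{hap_freq} (frequency of the first block
#'   haplotype, default 0.4).
#' @return list of class \code{sim_dataset}; \code{truth$block} records the
#'   planted range.
#' @export
plant_ld_block <- function(config, block_spec) {
  bs <- block_spec
  m <- config$markers_per_chromosome
  if (is.null(bs$hap_freq)) bs$hap_freq <- 0.4
  if (bs$chrom < 1 || bs$chrom > config$n_chromosomes)
    stop("block chromosome outside the map")
  if (bs$from < 1 || bs$to > m || bs$from > bs$to)
    stop("block marker range outside the map")
  if (bs$to - bs$from + 1L < 2L)
    stop("a planted block needs at least 2 markers")
  set.seed(config$seed)
  map <- .sim_map(config)
  n <- config$sample_size
  chunks <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    H <- matrix(stats::rbinom(2L * n * m, 1L, rep(p0, each = 2L * n)),
                2L * n, m)
    if (ch == bs$chrom) {
      w <- bs$from:bs$to
      # two complementary haplotypes: all-1 vs all-0 across the block
      carrier <- stats::rbinom(2L * n, 1L, bs$hap_freq)
      H[, w] <- matrix(carrier, 2L * n, length(w))
    }
    chunks[[ch]] <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  }
  g <- geno_matrix(do.call(cbind, chunks), map,
                   ids = sprintf("pl_%03d", seq_len(n)))
  structure(list(genotypes = g,
                 truth = list(config = config, block = bs)),
            class = "sim_dataset")
}

#' Fixed worked-example inputs
#'
#' Small fixed tables used throughout the documentation and tests: a
#' phase-unambiguous two-locus table, the double-heterozygote-only table
#' (the EM stationary point), a 10-individual mixed table for checking the
#' EM against a likelihood grid, and an inbreeding-count example.
#'
#' @return named list: \code{phase_known}, \code{double_het_only},
#'   \code{em_mixed} (3x3 count matrices) and \code{inbreeding_counts}
#'   (list O, E, L).
#' @export
worked_example_tables <- function() {
  t1 <- matrix(0L, 3, 3); t1[3, 3] <- 2L; t1[1, 1] <- 2L
  t2 <- matrix(0L, 3, 3); t2[2, 2] <- 4L
  t3 <- matrix(0L, 3, 3)
  t3[3, 3] <- 3L; t3[1, 1] <- 3L; t3[2, 2] <- 2L; t3[3, 2] <- 1L
  t3[2, 3] <- 1L
  dn <- list(d1 = 0:2, d2 = 0:2)
  dimnames(t1) <- dimnames(t2) <- dimnames(t3) <- dn
  list(phase_known = t1, double_het_only = t2, em_mixed = t3,
       inbreeding_counts = list(O = 70, E = 60, L = 100))
}

#' Write a simulated dataset to disk
#'
#' Emits .ped/.map and VCF via the package writers plus a YAML truth
#' record.
#'
#' @param dataset a \code{sim_dataset}.
#' @param dir output directory (created if needed).
#' @param basename file stem (default "sim").
#' @return Invisibly, the paths written.
#' @export
write_sim_dataset <- function(dataset, dir, basename = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- file.path(dir, paste0(basename, ".ped"))
  mp <- file.path(dir, paste0(basename, ".map"))
  vcf <- file.path(dir, paste0(basename, ".vcf"))
  truth <- file.path(dir, paste0(basename, "_truth.yml"))
  write_ped_map(dataset$genotypes, ped, mp)
  write_vcf(dataset$genotypes, vcf)
  tr <- dataset$truth
  tr$haplotypes <- NULL  # keep the record small and textual
  tr$config <- unclass(tr$config)
  if (!is.null(tr$pedigree)) tr$pedigree <- as.list(tr$pedigree)
  yaml::write_yaml(tr, truth)
  invisible(c(ped = ped, map = mp, vcf = vcf, truth = truth))
}
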