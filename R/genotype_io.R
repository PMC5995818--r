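#' Genotype matrix with marker map
#'
#' Container for diploid biallelic SNP genotypes. Genotypes are stored as the
#' dosage of allele A (the first allele encountered in a .ped file, or the
#' REF allele of a VCF): 0, 1, 2 or \code{NA} for missing. The companion
#' marker map gives, for every marker, its chromosome label, identifier and
#' 1-based physical position in base pairs.
#'
#' @param geno integer matrix, individuals x markers, values in
#'   \{0, 1, 2, NA\}.
#' @param map data.frame with columns \code{chrom} (character), \code{id}
#'   (character, unique) and \code{pos} (positive integer bp, strictly
#'   increasing within each chromosome).
#' @param ids character vector of individual identifiers (defaults to
#'   \code{rownames(geno)} or \code{ind_1 ... ind_n}).
#' @param alleles optional data.frame with columns \code{a1} (allele A) and
#'   \code{a2} per marker; used when writing .ped or VCF output.
#' @return An object of class \code{geno_matrix}: a list with elements
#'   \code{geno}, \code{map}, \code{ids}, \code{alleles}.
#' @export
geno_matrix <- function(geno, map, ids = NULL, alleles = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "id", "pos") %in% names(map)))
  map$chrom <- as.character(map$chrom)
  map$id <- as.character(map$id)
  map$pos <- as.integer(map$pos)
  if (ncol(geno) != nrow(map))
    stop("geno has ", ncol(geno), " columns but map has ", nrow(map), " rows")
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(map$id))
    stop("marker identifiers must be unique")
  if (any(map$pos <= 0L))
    stop("marker positions must be positive")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(ids)) {
    ids <- rownames(geno)
    if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(geno)))
  }
  if (length(ids) != nrow(geno))
    stop("length(ids) must equal nrow(geno)")
  if (is.null(alleles)) {
    alleles <- data.frame(a1 = rep("A", nrow(map)), a2 = rep("B", nrow(map)),
                          stringsAsFactors = FALSE)
  }
  dimnames(geno) <- list(as.character(ids), map$id)
  structure(list(geno = geno, map = map, ids = as.character(ids),
                 alleles = alleles),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "individuals x", ncol(x$geno),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

# subset a geno_matrix by individual and/or marker index
subset_geno <- function(g, individuals = NULL, markers = NULL) {
  if (is.null(individuals)) individuals <- seq_len(nrow(g$geno))
  if (is.null(markers)) markers <- seq_len(ncol(g$geno))
  geno_matrix(g$geno[individuals, markers, drop = FALSE],
              g$map[markers, , drop = FALSE],
              ids = g$ids[individuals],
              alleles = g$alleles[markers, , drop = FALSE])
}

#' Read PLINK text .ped/.map files
#'
#' Parses whitespace-delimited PLINK text files into a \code{geno_matrix}.
#' Allele A at each marker is the first non-missing allele encountered
#' (individuals in file order, first allele column before the second); a
#' genotype containing the missing code \code{"0"} becomes \code{NA}.
#' Because the file itself defines the orientation, writing a matrix and
#' reading it back preserves genotypes always, and preserves dosages
#' exactly when each marker's first listed carrier carries allele A;
#' orientation-invariant statistics (MAF, |D'|, r2) are unaffected either
#' way.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file (chrom, id, [cM,] bp).
#' @return A \code{geno_matrix}.
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  mp <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                          data.table = FALSE)
  if (ncol(mp) == 3L) {
    map <- data.frame(chrom = mp[[1]], id = mp[[2]], pos = as.integer(mp[[3]]),
                      stringsAsFactors = FALSE)
  } else if (ncol(mp) >= 4L) {
    map <- data.frame(chrom = mp[[1]], id = mp[[2]], pos = as.integer(mp[[4]]),
                      stringsAsFactors = FALSE)
  } else stop("map file must have 3 or 4 columns")
  pd <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                          data.table = FALSE)
  m <- nrow(map)
  if (ncol(pd) != 6L + 2L * m)
    stop("ped row length ", ncol(pd), " does not match 6 + 2*", m,
         " expected from map")
  ids <- pd[[2]]
  n <- nrow(pd)
  geno <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- pd[[6L + 2L * j - 1L]]
    x2 <- pd[[6L + 2L * j]]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    # allele order: first allele encountered scanning individuals in order,
    # first allele column before second
    al <- character(0)
    for (i in which(!miss)) {
      if (!(x1[i] %in% al)) al <- c(al, x1[i])
      if (!(x2[i] %in% al)) al <- c(al, x2[i])
      if (length(al) >= 3L) break
    }
    if (length(al) > 2L)
      stop("marker ", map$id[j], " has more than two alleles: ",
           paste(sort(unique(obs)), collapse = ","))
    if (length(al) == 0L) al <- c("A", "B")
    if (length(al) == 1L) al <- c(al, if (al == "A") "B" else "A")
    d <- (x1 == al[1]) + (x2 == al[1])
    d[miss] <- NA_integer_
    geno[, j] <- as.integer(d)
    a1[j] <- al[1]; a2[j] <- al[2]
  }
  geno_matrix(geno, map, ids = ids,
              alleles = data.frame(a1 = a1, a2 = a2, stringsAsFactors = FALSE))
}

#' Write PLINK text .ped/.map files
#'
#' Deterministic, byte-stable serialization of a \code{geno_matrix}. Missing
#' genotypes are written as \code{"0 0"}.
#'
#' @param genotypes a \code{geno_matrix}.
#' @param ped_path,map_path output paths.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_ped_map <- function(genotypes, ped_path, map_path) {
  g <- genotypes
  m <- ncol(g$geno)
  map_lines <- paste(g$map$chrom, g$map$id, 0, g$map$pos, sep = "\t")
  ok <- tryCatch({
    writeLines(map_lines, map_path); TRUE
  }, error = function(e) stop("cannot write map file: ", map_path))
  n <- nrow(g$geno)
  allele_field <- function(d, a1, a2) {
    out <- rep("0 0", length(d))
    out[!is.na(d) & d == 2L] <- paste(a1, a1)
    out[!is.na(d) & d == 1L] <- paste(a1, a2)
    out[!is.na(d) & d == 0L] <- paste(a2, a2)
    out
  }
  cols <- vapply(seq_len(m), function(j)
    allele_field(g$geno[, j], g$alleles$a1[j], g$alleles$a2[j]),
    character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  if (m == 0L) cols <- matrix(character(0), nrow = n, ncol = 0L)
  lead <- paste("FAM", g$ids, 0, 0, 0, -9)
  body <- if (m > 0L) paste(lead, apply(cols, 1L, paste, collapse = " "))
          else lead
  tryCatch(writeLines(body, ped_path),
           error = function(e) stop("cannot write ped file: ", ped_path))
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a VCF into a genotype matrix
#'
#' Reads a VCF (v4.x) with a GT FORMAT field. Dosage counts the REF allele,
#' so \code{0/0 -> 2}, \code{0/1 -> 1}, \code{1/1 -> 0}, \code{./. -> NA};
#' both \code{/} and \code{|} separators are accepted. Records that are not
#' biallelic SNVs are skipped and counted.
#'
#' @param vcf_path path to an (uncompressed or gzipped) VCF.
#' @return A \code{geno_matrix}; the number of skipped non-biallelic records
#'   is available as \code{attr(x, "n_skipped")}.
#' @export
read_vcf <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fmt <- v@gt[, 1]
  if (nrow(v@gt) == 0L || !any(grepl("GT", fmt)))
    stop("VCF has no GT field")
  bi <- vcfR::is.biallelic(v)
  n_skipped <- sum(!bi)
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  # count REF allele per genotype string
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 2L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 0L
  fix <- vcfR::getFIX(v)
  if (nrow(gt) == 1L) fix <- matrix(fix, nrow = 1L,
                                    dimnames = list(NULL, names(fix)))
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  map <- data.frame(chrom = fix[, "CHROM"], id = id,
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  out <- geno_matrix(t(dose), map, ids = colnames(gt),
                     alleles = data.frame(a1 = fix[, "REF"], a2 = fix[, "ALT"],
                                          stringsAsFactors = FALSE))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 with unphased GT genotypes; allele A becomes REF.
#'
#' @param genotypes a \code{geno_matrix}.
#' @param vcf_path output path.
#' @return Invisibly, the path written.
#' @export
write_vcf <- function(genotypes, vcf_path) {
  g <- genotypes
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$ids), collapse = "\t"))
  m <- ncol(g$geno)
  gt_code <- c(`0` = "1/1", `1` = "0/1", `2` = "0/0")
  rows <- vapply(seq_len(m), function(j) {
    d <- g$geno[, j]
    gt <- rep("./.", length(d))
    gt[!is.na(d)] <- gt_code[as.character(d[!is.na(d)])]
    paste(c(g$map$chrom[j], g$map$pos[j], g$map$id[j],
            g$alleles$a1[j], g$alleles$a2[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  tryCatch(writeLines(c(hdr, rows), vcf_path),
           error = function(e) stop("cannot write VCF: ", vcf_path))
  invisible(vcf_path)
}

#' Per-marker allele statistics
#'
#' Computes, for each marker, the allele-A frequency, minor allele frequency,
#' call rate and genotype counts from dosages, using non-missing genotypes
#' only. Markers with no non-missing genotype are flagged and get an
#' undefined (NA) frequency.
#'
#' @param genotypes a \code{geno_matrix} or a dosage matrix.
#' @return data.frame with one row per marker: \code{id}, \code{chrom},
#'   \code{pos}, \code{n_AA}, \code{n_Aa}, \code{n_aa}, \code{n_missing},
#'   \code{call_rate}, \code{p_A}, \code{maf}, \code{all_missing}.
#' @export
allele_stats <- function(genotypes) {
  if (inherits(genotypes, "geno_matrix")) {
    geno <- genotypes$geno
    map <- genotypes$map
  } else {
    geno <- as.matrix(genotypes)
    map <- data.frame(chrom = NA_character_,
                      id = paste0("m", seq_len(ncol(geno))),
                      pos = NA_integer_)
  }
  n <- nrow(geno)
  n_AA <- colSums(geno == 2L, na.rm = TRUE)
  n_Aa <- colSums(geno == 1L, na.rm = TRUE)
  n_aa <- colSums(geno == 0L, na.rm = TRUE)
  n_missing <- colSums(is.na(geno))
  nonmiss <- n - n_missing
  p_A <- ifelse(nonmiss > 0, (2 * n_AA + n_Aa) / (2 * nonmiss), NA_real_)
  data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
             n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa, n_missing = n_missing,
             call_rate = nonmiss / n,
             p_A = p_A,
             maf = pmin(p_A, 1 - p_A),
             all_missing = nonmiss == 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}
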