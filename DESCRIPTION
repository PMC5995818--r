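Package: ldscape
Title: Linkage Disequilibrium Characterization for SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes linkage disequilibrium (LD) in diploid biallelic
    SNP panels: quality control (call rate, minor allele frequency,
    Hardy-Weinberg chi-square), EM haplotype-frequency estimation from
    unphased genotypes with the |D'| and r-squared statistics, per-chromosome
    and distance-binned LD summaries, excess-homozygosity inbreeding
    coefficients, the VanRaden genomic relationship matrix, effective
    population size trajectories from the Sved relation between r-squared and
    recombination rate, Gabriel-style haplotype blocks from |D'| confidence
    intervals, and a marker-density recommendation. A forward Wright-Fisher
    simulator with recombination provides genotype data with known ground
    truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
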