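---
title: "Characterizing linkage disequilibrium in SNP panels with ldscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing linkage disequilibrium in SNP panels with ldscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldscape)
```

## The problem

Genomic selection and association mapping rely on linkage disequilibrium
(LD) between genotyped markers and unobserved causal variants. Whether a
given SNP panel is dense enough for a population therefore comes down to an
empirical question: how fast does LD decay with physical distance in that
population, how large are its haplotype blocks, and what do those imply
about its recent effective population size and the marker density needed?
`ldscape` implements this analysis end to end for diploid biallelic SNP
data — the setting of livestock panels such as the ovine HD chip, where a
few hundred animals are genotyped at tens of thousands of SNPs spread over
26 autosomes — together with a forward Wright–Fisher simulator that
provides datasets with known truth, so every stage of the pipeline can be
validated without access to any particular animal dataset.

## Models and procedures

### Two-locus LD from unphased genotypes

For two biallelic markers with allele frequencies $\rho_A$ and $\rho_B$ and
haplotype frequency $\rho_{AB}$, the package reports

$$D = \rho_{AB} - \rho_A\rho_B, \qquad
|D'| = \frac{|D|}{D_{max}}, \qquad
r^2 = \frac{D^2}{\rho_A\rho_a\rho_B\rho_b},$$

where $D_{max} = \min(\rho_A\rho_b, \rho_a\rho_B)$ when $D > 0$ and
$\min(\rho_A\rho_B, \rho_a\rho_b)$ in magnitude when $D < 0$; $D = 0$ is
reported as $|D'| = 0$. Unphased genotypes leave one ambiguity — the double
heterozygote may be $AB/ab$ or $Ab/aB$ — so $\rho_{AB}$ is estimated by
maximum likelihood with an EM algorithm: the E-step splits double
heterozygotes in proportion to $\rho_{AB}\rho_{ab}$ versus
$\rho_{Ab}\rho_{aB}$ and the M-step re-estimates the four haplotype
frequencies from expected counts. Marginal allele frequencies are invariant
under these iterations, so the estimate always stays in the admissible
range $[\max(0, \rho_A+\rho_B-1),\ \min(\rho_A, \rho_B)]$.

Numerical choices worth knowing about:

* **Starts.** EM runs from the linkage-equilibrium point
  $\rho_{AB} = \rho_A\rho_B$, which is deterministic but is a stationary
  point whenever the phase-known part of the table is itself at
  equilibrium. Two further deterministic starts (the quartile points of the
  admissible range) and the two range endpoints are therefore evaluated,
  and the highest-likelihood solution wins. The endpoints matter because a
  boundary maximum — an absent haplotype, hence $|D'| = 1$ — is approached
  by EM only sublinearly.
* **The saddle table.** A table containing *only* double heterozygotes
  carries no phase information; its likelihood is maximized at $|D'| = 1$
  on both boundaries, but symmetrically, with no evidence for either
  phase. The package keeps the equilibrium solution ($D = 0$) for such
  tables and flags them (`saddle`), which is the conservative report.
* **Tolerances.** Convergence is declared when the largest frequency
  change drops below $10^{-8}$ (cap 1000 iterations). On an exhaustive
  enumeration of all two-locus tables with up to 8 individuals, the EM
  solution's log-likelihood matches a fine-grid search to within
  $10^{-6}$.
* **Missing data** are never imputed; each pair uses its
  pairwise-complete individuals, and pairs whose complete subset leaves a
  marker monomorphic are skipped and counted.

### Confidence intervals for $|D'|$ and haplotype blocks

Block finding needs interval estimates of $|D'|$, not points: with modest
sample sizes $|\hat{D}'|$ is biased upward, and the Gabriel-style
criterion classifies marker pairs by whether their $|D'|$ interval shows
*strong LD* (lower bound $\ge 0.70$, upper bound $\ge 0.98$) or *strong
recombination* (upper bound $< 0.90$). The package profiles the genotype
log-likelihood over $\rho_{AB}$, converts to $|D'|$, and takes the
likelihood-ratio interval at level 0.90 (all values within
$\chi^2_1(0.90)/2$ log-units of the maximum). A candidate run of markers
becomes a block when it spans at most 500 kb (configurable), has at least
one informative pair, and its strong-LD fraction among informative pairs
reaches 0.95; overlaps are resolved greedily, longest span first, ties to
the smaller start position. All thresholds sit in `block_config()` and
follow the defaults popularized by the standard block-finding tools.

The marker-density recommendation is the ratio of genome length to the
mean within-block intermarker distance — the spacing at which markers tag
haplotypes rather than recombination gaps.

### Inbreeding and relatedness

The individual inbreeding coefficient is the excess-homozygosity
method-of-moments estimator
$F_i = (O_i - E_i)/(L_i - E_i)$ over each individual's non-missing loci.
The expected homozygosity uses the small-sample-corrected per-locus
heterozygosity $2p(1-p)\cdot 2n/(2n-1)$ — the estimator used by the common
SNP toolkits — which makes $\bar F$ unbiased around zero in an unrelated
sample; `sample_correction = FALSE` gives the plain $2p(1-p)$ form.
Negative values occur exactly when fewer homozygous loci are observed than
expected. Relationships come from the VanRaden (method 1) genomic
relationship matrix $G = ZZ'/(2\sum_j p_j(1-p_j))$ with dosages centered
at $2p_j$; with in-sample frequencies the mean off-diagonal is forced
slightly negative (about $-\bar{G}_{ii}/n$), which is visible in the
half-sib checks below and is a property of the estimator, not a bug.

### Effective population size from LD decay

Under drift–recombination balance the Sved relation links expected
$r^2$ to recombination rate: $E[r^2] = (1 + 4N_ec)^{-1}$. Binning all
within-chromosome pairs by distance, mapping distance to Morgans at
1 cM/Mb (configurable), and inverting per bin gives a trajectory

$$N_e(t) = \frac{1}{4c_t}\left(\frac{1}{E[r^2 \mid c_t]} - \alpha\right),
\qquad t = \frac{1}{2c_t},$$

with $\alpha \in \{1, 2, 2.2\}$ the mutation adjustment ($1$: no
mutation; $2.2$: mutation–drift equilibrium). Per-chromosome $N_e$ is the
harmonic mean over that chromosome's usable bins; the "recent" $N_e$ is
the usable bin with the largest $c$.

Two practical points, both verified by simulation in the test suite:

* **Sampling correction.** The EM-based $\hat r^2$ is inflated by
  sampling. Measured on unlinked (between-chromosome) pairs in
  Wright–Fisher simulations, the inflation is close to one over the number
  of sampled *chromosomes*, $1/(2n)$ for $n$ diploids — not $1/n$ — so
  that is what `ne_trajectory()` subtracts when the correction is on.
* **Where the hyperbola holds.** At drift equilibrium without mutation,
  $1/E[r^2]$ behaves like $4Nc + 3$ rather than $4Nc + 1$, so the
  $\alpha = 1$ inversion carries a relative bias of roughly $2/(4Nc)$:
  large at short distances, a few percent once $4Nc \gtrsim 20$. Recovery
  experiments therefore read the recent $N_e$ from a wide far-distance bin
  (3–9 Mb at the default spacing), where the bias is small and the pair
  count is large.

The package also exposes the one-generation decay recursion
$E(D_t) = (1-c)(1 - \frac{1}{2N_e})E(D_{t-1})$ and the closed-form
drift–inbreeding expectation
$E(D^2) = \frac{1}{15}p_0(1-p_0)q_0(1-q_0)[6(1-F) - 5(1-F)^3 - (1-F)^6]$,
used to correlate predicted with observed squared disequilibrium across
chromosomes.

### Quality control

`run_qc()` fixes the filter order so audit reports are deterministic:
non-autosomal markers out first, then samples with call rate $< 0.90$,
then — with statistics recomputed on the retained samples — SNPs by call
rate $< 0.90$, MAF $< 0.05$, and Hardy–Weinberg $\chi^2$ p-value $< 0.1$
(plain 1-df test, no continuity correction; monomorphic markers pass, as
the test carries no evidence against HWE). All comparisons are strict, a
SNP failing several filters is attributed to the first, and the
per-chromosome before/after table conserves counts by construction.
Because the sample filter precedes the SNP filters, idempotence of the
whole protocol is a property of panel-sized data (where removing a few
SNPs barely moves sample call rates), not a theorem; the suite tests it at
realistic marker counts.

## The synthetic-data generator

`simulate_wright_fisher()` is a discrete-generation, constant-size,
randomly mating diploid Wright–Fisher model with recombination and no
mutation: each offspring draws two parents with replacement; each gamete
picks a random leading strand and a Poisson number of crossovers in the
chromosome's genetic length, at uniform positions. Defaults emulate the
structure of an ovine HD panel — 26 autosomes, 0.07 Mb regular spacing,
1 cM/Mb, initial allele frequencies uniform on $[0.2, 0.5]$ (mean MAF
0.35), diploid size 100 with the full population sampled — at a reduced
per-chromosome marker count (150) so a simulation runs in seconds. The
burn-in default is 100 generations: LD at the distances analysed
equilibrates on the $1/(2c)$ timescale (tens of generations) while
polymorphism is lost on the $N$ timescale, so a burn-in of about $N$
equilibrates LD without fixing most markers. All randomness flows through
R's default Mersenne–Twister generator via `set.seed(seed)`, making
datasets byte-identical across platforms for a given seed.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: mutation, selection and migration; varying
recombination rate along chromosomes; genotyping error; ascertainment bias
of array SNPs; and cross-chromosome dependence (chromosomes are simulated
as independent replicates, which understates the genealogical correlation
a single pedigree imposes). `make_pedigreed_sample()` adds known half-sib
and full-sib structure on top of unrelated founders;
`plant_ld_block()` builds two-haplotype blocks in otherwise independent
markers for block-detection tests.

## Validation experiments shipped in the test suite

* EM versus an exhaustive fine-grid likelihood oracle on every table with
  $\le 8$ individuals, and versus direct haplotype counting on
  phase-known fixtures.
* $0 \le r^2 \le |D'| \le 1$ over $10^5$ random frequency configurations,
  and invariance of both statistics under marker swap and allele
  relabeling.
* Round-trip of the Sved relation ($N_e \to E[r^2] \to N_e$, relative
  error $< 10^{-6}$), and recovery of the true $N$ within ±30% from
  simulated panels at $N = 50, 100, 200$ (chromosome count scaled up at
  small $N$, where genealogical variance of mean $r^2$ dominates).
* Exact recovery of planted block boundaries in 20 seeded simulations.
* $\bar F$ within 3 SE of zero on unrelated panels; half-sib mean
  relationship within 3 SE of 0.25 across 25 simulated sire families.
* Byte-identical report bundles for identical input and configuration.

Problem sizes in the suite (hundreds of markers, tens to hundreds of
individuals, up to 40 simulated chromosomes for the $N = 50$ recovery) are
the package's chosen compromise between statistical power and a test suite
that runs in about a minute and a half.

## Worked example

```{r example}
ds <- simulate_wright_fisher(
  sim_config(N = 100, n_chromosomes = 2, markers_per_chromosome = 80,
             generations = 100, seed = 5))
bundle <- run_full_analysis(ds$genotypes)
bundle
head(bundle$chrom_summary_adjacent)
```

## Known limitations

* The Sved inversion inherits the approximations discussed above; the
  trajectory is a descriptive summary, not a likelihood-based demographic
  fit, and no confidence intervals are attached to $N_e$.
* $|D'|$ intervals use the profile likelihood with margins fixed at their
  sample values; uncertainty in the allele frequencies themselves is not
  propagated.
* Dosage orientation of `.ped` input follows the file (allele A is the
  first allele encountered), so orientation-dependent quantities (signed
  $D$, $\rho_A$) are defined relative to the file; MAF, $|D'|$, $r^2$, F
  and G are orientation-invariant.
* Inter-chromosomal LD is not computed, and blocks are bounded at 500 kb
  by default; both are deliberate scope choices.
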