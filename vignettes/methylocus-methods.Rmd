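---
title: "Methods: allele-aware locus-scale methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-aware locus-scale methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylocus)
```

# Scope and model

`methylocus` analyses DNA methylation at a single candidate locus (on the
order of 10 kb) in a cohort of individuals, paying explicit attention to
*polymorphic CpG sites* (polyCpGs): SNPs at the C or G of a CpG dinucleotide,
so that one allele carries a methylatable CpG and the other does not. The
pipeline has four stages:

1. **Landscape** — CpG density in sliding windows, CpG-island prediction,
   island subdivision at local density minima, and partition of the locus
   into named gene features (islands, promoter, island compartments, intron,
   enhancer, shores).
2. **Quantification** — trimming and ungapped bisulfite-aware alignment of
   targeted amplicon reads against an IUPAC *ambiguity reference*, per-CpG
   methylation extraction, conversion-efficiency estimation from non-CpG
   cytosines, and genotype calling at polyCpGs from the conversion-safe
   strand.
3. **Structure and association** — pairwise co-methylation and its decay
   with distance within and between features, cross-platform concordance,
   differential methylation between expression groups, genotype tests, and
   regression of expression on three polyCpG measures.
4. **Synthesis** — a generator producing locus, cohort, methylation
   landscape, expression and reads with complete ground truth, so that each
   stage above can be validated by parameter recovery.

# The ambiguity reference and why alignment is allele-aware

Bisulfite conversion turns unmethylated C into T (and, seen from the
opposite strand, G into A). Aligning converted reads against a plain
reference biases coverage toward the reference allele at SNPs, and at
polyCpGs it systematically confounds the alternative allele with
unmethylated signal. The package therefore builds a modified reference in
which every SNP inside a CpG is written as the CpG allele (C at the C, G at
the G) and every other SNP is replaced by the IUPAC code covering both
alleles (`build_bisulfite_reference()`). During alignment a reference
ambiguity code matches any of its bases *before* the conversion rule is
applied, so neither allele is penalized.

Alignment itself (`align_bisulfite()`) is an exhaustive ungapped scan — the
appropriate tool at amplicon scale, where reads have no indels and the
reference is a few kilobases. Reads are tested in the two conversion frames
of a directional library (original-top: read C may appear as T under a
reference C; original-bottom, in top orientation: G may appear as A), and a
read is reported only at a unique best placement with at most `max_mismatch`
(default 3 per 130 bp) mismatches; ties within or across frames leave it
unmapped rather than placed arbitrarily. Mate 2 is reverse-complemented into
top orientation before frame selection. The inner scan loop is compiled
(Rcpp) because it runs once per candidate offset per read.

Design choices worth stating:

* **Directional library.** Only OT/OB frames are modelled, matching
  standard bisulfite amplicon kits; complementary-to-OT/OB frames are not.
* **Mate overlap.** Overlapping mate bases are counted once per fragment,
  first mate wins — double-counting would overweight fragment middles.
* **Unmapped is a status**, counted in the `unmapped` attribute, never an
  error.

# Methylation, conversion and genotypes

At each catalogued CpG, OT fragments vote through the C (C = methylated,
T = unmethylated) and OB fragments through the G (G = methylated,
A = unmethylated); other bases are ignored. A site with zero coverage is
`NA`, never 0. Cytosines outside CpG context (CHH/CHG on either strand,
contexts with a SNP excluded) are expected to be unmethylated in this assay,
so their apparent methylation estimates the bisulfite conversion *failure*
rate: `conversion = 1 - mean non-CpG methylation`. Note the corollary used
in the validation suite: with conversion efficiency `e`, the *apparent*
methylation of a site with true methylation `p` is `p + (1 - p)(1 - e)`;
the estimator reproduces the apparent value, and the chemistry offset is a
property of the assay, not of the estimator.

Genotypes at polyCpGs are the number of CpG-bearing alleles (0/1/2), read
only from the strand whose base is untouched by conversion: OB reads when
the SNP is at the C (the complementary G is conversion-safe), OT reads when
it is at the G. The CpG-allele read fraction `f` maps to genotype 2 when
`f > 0.9`, 0 when `f < 0.1`, 1 when `|f - 0.5| <= 0.15`, otherwise unknown;
calls need at least 10 informative reads. These bands are deliberately
conservative: an ambiguous `f` (e.g. 0.7) yields an unknown rather than a
guess.

The three polyCpG measures compared in the association stage are
`total_meth` (fraction of all covering reads carrying a methylated CpG,
regardless of genotype), `genotype`, and `meth_per_cpg` (methylation per
CpG-bearing allele: equal to `total_meth` for CpG homozygotes, twice it for
heterozygotes, undefined without a CpG allele). Heterozygote values can
exceed 1 through sampling noise and are clipped at 1 with a warning.

# Landscape computations

CpG islands are predicted with the traditional criteria — length > 200 bp,
G+C > 0.5, observed/expected CpG ratio > 0.6 in a 300 bp window — by
merging overlapping passing windows into maximal runs. The obs/exp ratio is
`N_CpG * L / (N_C * N_G)`, defined as 0 when a window has no C or no G (such
a window cannot pass the threshold anyway). Boundary semantics (first
passing window start to last passing window end) are declared and tested by
construction; agreement with any particular island web tool is expected only
to within one window, which is also the tolerance used in the recovery
tests.

Island subdivision smooths the within-island CpG-count curve with a centred
moving average (halfwidth 25 steps) and splits at internal local minima.
Two guards keep this from fragmenting an island on noise: a minimum must be
*prominent* (below the smaller flanking maximum by at least 25% of the
within-island density range) and minima closer than one window collapse to
the lowest. Plateau minima split at the plateau midpoint.

The feature map is assembled from the islands, the TSS, the second-island
compartments and the enhancer interval, with overlaps resolved by a fixed
priority (islands/compartments > promoter > enhancer > intron > shore >
other). The enhancer is always an *input* (in practice delineated by
H3K4me1 chromatin immunoprecipitation); the package never infers it. Shores
default to 2 kb island flanks.

Coordinates are 1-based inclusive everywhere inside the package — the R
convention — and converted to 0-based half-open only in the BED writer.

# Statistical choices

* **t-tests** between expression groups are Welch (unequal variance),
  two-sided. Sites constant in both groups get p = 1 by convention.
* **Multiple testing** uses Benjamini–Hochberg step-up (`p.adjust`),
  validated in the suite against a from-definition oracle.
* **The variant-spectrum test** is a six-class goodness of fit against a
  uniform expectation (df = 5), the form matching the degrees of freedom
  reported for such spectra. The test exposes its count vector so the
  arithmetic is auditable; on the canonical count vector (13, 1, 2, 2, 1,
  10) it gives chi-square 28.72.
* **Fisher's exact test** is two-sided by the point-probability method
  (summing all tables whose hypergeometric probability does not exceed the
  observed table's) — the method behind `fisher.test` and the common online
  calculators, validated against exhaustive enumeration.
* **Kendall's tau** is the tie-corrected tau-b; ties are guaranteed with
  0/1/2 genotype scores.
* **Median split** sends strict exceeders of the median to the high group;
  exact ties alternate deterministically in sorted-identifier order into the
  smaller group, so group sizes differ by at most one, and an all-equal
  vector is an error.
* **Permutation p-values** are always the add-one form
  `(1 + #{null >= observed}) / (n_perm + 1)`, which is valid (conservative)
  at any `n_perm`, and every permutation routine takes an explicit seed and
  reports it, making results bit-reproducible.
* **Distance decay** regresses pairwise co-methylation on distance, a
  same-feature indicator and their interaction. The permutation null
  shuffles the site positions (with their feature labels) over the columns
  of the *fixed* correlation matrix: this destroys the distance structure
  while exactly preserving the empirical correlation distribution. Shuffling
  individuals instead would also destroy the correlations themselves, which
  is a different (stronger) null than the question asks. This choice is an
  interpretation; it is stated here rather than claimed to be the only one.
* **Pairwise-complete** observations are used in all correlation matrices;
  cells with fewer than `min_individuals` (default 5) complete pairs are
  `NA`. Note the invariance that holds and is tested: per-*site* positive
  affine rescaling leaves the correlation matrix unchanged (per-individual
  rescaling does not, and no such claim is made).
* **PWM allele affinity** is a best-hit log-odds comparison (pseudocount
  0.1, both strands, all placements within the window), not a biophysical
  affinity model; it ranks motifs by the absolute allele difference in best
  score and can BH-adjust externally supplied motif p-values.

# The synthetic-data generator

The generator's defaults describe a locus and cohort with the statistical
structure of the system the package targets:

* **Locus** (`generate_locus`): 8 kb; a 0.4 kb island 0.2–0.6 kb upstream
  of the TSS; a 1.3 kb island over the first exon built from three dense
  blocks separated by 100 bp sparse spacers (tri-modal density); an AT-rich
  inter-island gap of ~350 bp containing the TSS (the promoter); a 786 bp
  CpG-poor intronic enhancer carrying 12 CpG-capable sites. 30 polyCpGs are
  placed — 7 in the enhancer, 3 in islands, 20 elsewhere; one is
  multi-allelic — with classes drawn from a deamination-biased spectrum
  (weights 0.45/0.03/0.07/0.07/0.03/0.35 for CpA/CpC/CpT/ApG/GpG/TpG).
  Ten further non-CpG SNPs include three linked "defining" SNPs.
* **Cohort** (`generate_cohort`): 30 diploid individuals; the
  high-expression (HI) haplotype at frequency 1/6 (Hardy–Weinberg mix in
  expectation, i.e. roughly 21/8/1 LO/LO / HI/LO / HI/HI at n = 30); HI
  haplotypes lack four enhancer CpGs (the focal polyCpG plus three linked
  sites, each carried with linkage probability 0.9), so HI carriers have
  measurably fewer enhancer CpGs; all other variants segregate independently
  with uniform minor-allele frequencies in 0.05–0.4.
* **Methylation** (`simulate_methylation`): per individual a latent
  Gaussian field over the catalogued sites with covariance
  `exp(-d / 500 bp)`, pushed through a logistic link centred at
  feature-level means (islands/promoter ~0.01–0.08, distal island
  compartment ~0.45, intron/enhancer ~0.72, feature s.d. mapped to the logit
  scale by the delta method). Enhancer sites on HI alleles are shifted down
  by 0.2 on the probability scale; alleles without a CpG are `NA`. The
  logistic-Gaussian construction gives bounded, distance-correlated
  fractions; it does not attempt to model bimodal single-molecule states,
  cell-type mixtures, or amplification bias — so passing recovery tests
  demonstrates estimator correctness under this structure, not robustness to
  those real-data phenomena.
* **Expression** (`simulate_expression`): one of three mechanisms —
  expression follows total enhancer methylation (`density`), the CpG-allele
  count at the focal polyCpG (`tf_genotype`), or the per-CpG-allele
  methylation at the focal site (`tf_meth_sensitive`, taking 0 when no CpG
  allele exists, i.e. the factor has nothing to bind). Defaults are
  strong-effect regimes: baseline 5670, beta -6000 / -1500 / -5000 per
  predictor unit, noise s.d. 300, a signal-to-noise ratio of roughly 2–3.
  The regimes must be strong for regime *identification* to be a fair task:
  `total_meth` and `meth_per_cpg` at a site where most individuals are CpG
  homozygotes are structurally collinear, and at low signal-to-noise their
  sample correlations with expression tie so often that no method could
  separate them reliably.
* **Reads** (`simulate_reads`): directional protocol, equiprobable OT/OB,
  uniform fragment starts within five ~720 bp amplicons tiling the 3.6 kb
  target, fragment lengths 260–380 bp, 2 x 130 bp mates, conversion
  efficiency 0.97, sequencing error 0.001 per base. Coverage is the
  expected per-site read-pair depth (default 100).

All generators are bit-reproducible from their seeds, and every stochastic
result object records the seed it was produced with.

# Measurement models used in validation

Two measurement paths feed the validation suite. The *full* path simulates
FASTQ, trims, aligns and extracts; it is used for conversion-efficiency
recovery, mapping-rate, methylation-truth correlation and genotype
concordance, on three to four individuals at 50–100x (about 7,000 read
pairs per run — the statistics of interest are per-site, so a handful of
individuals already gives hundreds of (individual, site) observations). The
*fast* path (`simulate_counts`) draws methylated read counts binomially at
the stated coverage; it is used where a property needs hundreds of cohorts
(regime identification over 100 cohorts per mechanism; type-I-error
calibration over 500 null replicates; permutation calibration over 400
replicates), because the property under test concerns the statistics at a
given coverage, not the read-processing chain that the full path already
validates.

# Known limitations

* No PCR-duplicate or amplification-bias model; the possibility that
  GC-rich methylated fragments amplify better is noted but not modelled.
* Ungapped alignment: indels are out of scope by design (amplicons).
* No M-bias correction or per-base quality recalibration.
* Island prediction reproduces the traditional criteria, not any specific
  web tool's internal averaging; only within-one-window agreement should be
  expected.
* The chi-square spectrum statistic is the standard goodness of fit; other
  published formulations of "6 x 2" tests exist, which is why the count
  vector itself is part of the result.
* Co-methylation clusters are not detected algorithmically (heatmap
  inspection is the intended use); only the distance-decay regression is
  automated.
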