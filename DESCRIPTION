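Package: methylocus
Title: Allele-Aware Targeted Bisulfite Methylation Analysis of a Candidate Locus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Locus-scale analysis of DNA methylation, CpG polymorphism and gene
    expression at a candidate gene. Characterizes the CpG landscape (density
    profiles, island prediction, island subdivision, shores and named gene
    features), quantifies methylation from targeted paired-end bisulfite reads
    aligned against an IUPAC ambiguity reference so that fixed and polymorphic
    CpG sites are measured without allelic bias, calls genotypes at polymorphic
    CpGs from the conversion-safe strand, and computes allele-normalized
    methylation measures. Downstream statistics cover co-methylation and its
    decay with distance, cross-platform concordance by permutation, differential
    methylation between expression groups, genotype association tests, the
    polymorphic-CpG variant spectrum and distribution, and position-weight-matrix
    allele affinity. A synthetic-data module generates loci, cohorts,
    methylation landscapes, expression and bisulfite reads with full ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
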