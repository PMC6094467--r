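Package: gbsqtl
Title: Linkage Mapping and QTL Analysis for Outbred F1 Crosses from
    Genotyping-by-Sequencing Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic linkage maps and maps quantitative trait loci
    (QTLs) in full-sib families from two outbred diploid parents (CP
    populations), starting from per-SNP, per-individual allele read counts
    produced by genotyping by sequencing.  Provides read-support filtering,
    genotype calling by functional (errors-in-both-variables) regression on
    square-root allele counts, allocation of SNPs to chromosomes by marker
    regression against an anchor map, detection and recoding of null-allele
    segregation patterns, two-point recombination-fraction estimation by EM,
    marker ordering by weighted metric multidimensional scaling with a
    principal curve, map checking and order improvement with a hidden Markov
    model over the four offspring inheritance states, HMM-based QTL interval
    mapping with permutation-derived genome-wide thresholds, ripening-score
    trait construction by principal coordinates, and a synthetic-cross
    generator that emulates the imbalanced marker composition of a raspberry
    Glen Moy x Latham style population for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
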