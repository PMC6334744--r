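Package: sweepscan
Title: Selection-Signature Scans and Population-Genomic Statistics for
    SNP-Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genomic analysis of diploid biallelic
    SNP-array genotypes: quality control (autosome, missingness and minor
    allele frequency filters), linkage-disequilibrium pruning and decay,
    per-population diversity statistics (proportion polymorphic, expected
    and observed heterozygosity, inbreeding coefficient), population
    structure (PCA, Reynolds distances, tree-derived kinship, f3/f4
    statistics with block-jackknife errors), and a three-statistic
    selection-signature scan (windowed FST Z-scores, a kinship-aware FLK
    test with empirical chi-square scaling, and the cross-population
    haplotype statistic Rsb built on EHH/iES) with consensus
    candidate-region calling and gene annotation.  A seeded synthetic-data
    generator (Balding-Nichols drift, optional admixture, haplotype-copying
    LD, a localized hard sweep) exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
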