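Package: ssrdiv
Title: SSR Marker Diversity, Kinship Clustering and Fingerprinting for
    Tetraploid Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of simple sequence repeat (SSR) fingerprints in
    genebank collections of autotetraploid crops such as native potato.
    Bins observed fragment sizes into published allele intervals, builds
    binary presence/absence allele matrices, computes per-locus
    polymorphism information content (PIC), Dice similarity and UPGMA
    kinship dendrograms with cophenetic validation and Newick export,
    summarizes STRUCTURE-style log-likelihood tables with the Evanno
    delta-K statistic, searches minimal unique SSR fingerprints per
    accession, and tests genetic clusters for enrichment of tuber color
    classes and above-mean total phenolic or anthocyanin content. A
    synthetic-data module simulates genebank-like tetraploid genotypes
    with planted cluster structure and cluster-correlated pigment
    phenotypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
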