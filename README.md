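# ssrdiv

SSR marker diversity, kinship clustering and minimal fingerprinting for
tetraploid germplasm collections.

## What this package is for

Genebanks of clonally maintained autotetraploid crops — native potato
(*Solanum tuberosum*, 2n = 4x = 48) being the motivating case — are
characterized with simple sequence repeat (SSR) markers. Each locus is a
PCR with one primer pair; the observed fragment sizes are binned into
published allele intervals; and, because allele dosage cannot be read in
a tetraploid, the genotype is reduced to a binary band
presence/absence fingerprint. `ssrdiv` implements the analysis pipeline
a curator runs on such data:

* **Binning and matrix building** — classify observed sizes into allele
  bins (`center ± tolerance`, with nearest-center tie-breaking and
  multi-interval "or" bins), producing the accession × allele 0/1 matrix
  with an explicit missing-amplification mask
  (`binarize()`, `drop_failed_loci()`).
* **Diversity** — presence-based allele frequencies and per-locus
  polymorphism information content, PIC = 1 − Σ fᵢ², with panel-level
  aggregates (`diversity_summary()`), plus the Evanno ΔK second-difference
  statistic over external STRUCTURE-style log-likelihood tables
  (`evanno_delta_k()`).
* **Kinship** — Dice similarity (2·|shared| / (|A| + |B|)), UPGMA
  clustering with deterministic tie-breaking, cophenetic validation,
  k-group extraction with A–G style labels, and Newick export
  (`similarity_matrix()`, `upgma()`, `cut_k()`, `to_newick()`).
* **Fingerprints** — per accession, the minimal set of SSR loci whose
  combined band profile is unique in the collection, by exhaustive search
  with a greedy fallback, with a per-accession distinguishability
  certificate (`minimal_fingerprint()`, `fingerprint_all()`).
* **Cluster–phenotype association** — per-cluster counts of accessions
  above the mean total phenolic (TPC) or anthocyanin content, one-sided
  hypergeometric enrichment of CIP tuber color classes in genetic
  clusters with BH correction, class-mean fold-ratios, and ordinal
  color–content correlations (`above_mean_counts()`, `enrichment_test()`,
  `color_content_summary()`).
* **Simulation** — genebank-scale synthetic data (tetraploid SSR
  genotypes with planted K-cluster structure and cluster-correlated
  pigment phenotypes) for end-to-end validation (`simulate_dataset()`,
  `write_fixture_set()`).

Results are tibbles designed for dplyr/ggplot2 workflows, with
broom-style `tidy()`/`glance()` methods and `autoplot()` visualizations.
The bundled 20-locus potato reference panel (`reference_panel()`)
carries the published allele bins and PIC values used throughout the
examples.

## Worked example

```r
library(ssrdiv)

# published 20-locus panel: per-locus PIC and panel aggregates
glance(diversity_summary(reference_panel()))
#> # A tibble: 1 × 8
#>   n_loci mean_pic min_pic max_pic mean_alleles min_alleles max_alleles total_alleles
#> 1     20    0.773    0.43    0.91         6.55           2          13           131

# synthetic 290-accession genebank with 7 planted kinship clusters
sim <- simulate_dataset(simulation_config(), seed = 1)
m <- binarize(sim$genotypes, sim$panel)
m
#> # Binary allele matrix: 290 accessions x 176 allele columns (20 loci), 0 missing calls

s <- similarity_matrix(m)
tree <- upgma(1 - s)
cophenetic_correlation(1 - s, cophenetic_matrix(tree))
#> [1] 0.98

clusters <- cut_k(tree, 7)
adjusted_rand_index(clusters$cluster, sim$truth$cluster)
#> [1] 1

above_mean_counts(sim$phenotypes, clusters, "anthocyanin")
#> # Above-mean anthocyanin: population mean 46.47, 65/290 accessions above
#> # A tibble: 7 × 6
#>   cluster cluster_size n_above         p    p_adj significant
#> 1 A                 40       4 0.992     0.999    FALSE
#> 2 B                 38      18 0.000219  0.000766 TRUE
#> 3 C                 33      17 0.0000882 0.000617 TRUE
#> ...

glance(fingerprint_all(m))
#> # A tibble: 1 × 6
#>   n_accessions n_unresolved n_exact n_greedy median_size max_size
#> 1          290            0     290        0           2        3
```

The mean PIC of 0.77 (range 0.43–0.91) says the panel's loci are highly
discriminating; the cophenetic correlation near 1 says the UPGMA tree
faithfully represents the Dice distances; an adjusted Rand index of 1
means the 7-group cut recovered the planted kinship structure exactly;
the two flagged clusters are the ones simulated with purple-flesh bias
(high anthocyanin); and a median fingerprint of 2 loci means two
well-chosen markers usually suffice to identify an accession uniquely.

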