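---
title: "Methods: SSR diversity, kinship and fingerprinting in tetraploid genebanks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR diversity, kinship and fingerprinting in tetraploid genebanks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ssrdiv)
library(dplyr)
```

## The analytical problem

Genebanks of clonally propagated, autotetraploid crops such as native
potato (*Solanum tuberosum*, 2n = 4x = 48) are routinely characterized
with simple sequence repeat (SSR) markers: each locus is amplified with
one primer pair and the observed fragment sizes (bp) are classified into
published allele bins. Because allele dosage cannot be read from band
intensity in a tetraploid, the data are reduced to presence/absence: an
accession either shows a band in a bin or it does not. Everything
downstream — diversity statistics, kinship clustering, minimal
identification fingerprints, and cluster–phenotype association — operates
on this binary allele matrix. `ssrdiv` implements that full pipeline with
a simulator that reproduces the structure of such a collection, so every
stage can be validated end to end without access to any particular
genebank's raw data.

## Allele binning

A locus panel stores, per marker, allele bins of the form
*center ± tolerance* (tolerance 0 for a bare size). Published panels
sometimes list size alternatives ("196±2 or 199") that are counted as a
single allele; these are encoded as one bin holding several intervals
mapped to one label. An observed size is assigned to the bin whose
interval contains it; when printed intervals overlap (adjacent ±1 bins
share their boundary size), the bin with the nearest center wins and an
exact distance tie goes to the lower center. This rule is deterministic,
total over positive sizes, and reduces to plain interval lookup when bins
do not overlap. A size contained in no interval is *unassigned* — a value,
not an error: `binarize(strict = TRUE)` escalates it, the default drops it
with a warning, mirroring how a scoring lab would treat an off-ladder
band.

Missing amplification (a call with no product) is recorded in an explicit
mask rather than silently scored as all-absent, so that similarity can
either treat missing loci as absent bands (`"zeros"`, the default) or
drop them pair-wise (`"pairwise-complete"`). Loci that amplified in no
accession carry no information and are removed by `drop_failed_loci()`
before analysis. The bundled reference panel keeps the published size
ranges except where a listed allele center falls outside its own printed
range (two loci); there the range is widened to contain the center, since
the allele list, not the range summary, defines the bins.

## Diversity: presence-based PIC

For locus frequencies $f_i$, the polymorphism information content is

$$\mathrm{PIC} = 1 - \sum_i f_i^2,$$

bounded by $1 - 1/k$ for $k$ alleles. With dosage unobserved, $f_i$ is
computed from presence counts: the number of accessions carrying allele
$i$ divided by the total presence count at the locus. This is the
convention that matches binary SSR scoring of tetraploids; it is not an
estimate of gametic allele frequency and is not treated as one.
`diversity_summary()` also accepts a pre-tabulated per-locus PIC column
(as published panel tables provide), so panel-level aggregates can be
reproduced without raw genotypes:

```{r}
glance(diversity_summary(reference_panel()))
```

## Kinship: Dice similarity and UPGMA

Similarity between two binary fingerprints is the Dice coefficient
$s = 2a/(2a + b + c)$ (with $a$ shared bands and $b, c$ private bands),
which ignores shared absences — appropriate where an absent band can also
mean a failed or unscored allele. The corresponding dissimilarity
$d = 1 - s$ is **not** guaranteed to satisfy the triangle inequality; the
pipeline never assumes metricity, and the test suite exhibits a violating
triple.

UPGMA clustering repeatedly merges the closest pair of clusters, with the
distance from a merged cluster to any other equal to the size-weighted
average of its parts — equivalently, the unweighted mean over all original
cross-pair distances, which is the property the test oracle recomputes
from scratch. Node heights follow the molecular-clock convention
(height = merge distance / 2), making the tree ultrametric with
leaf-to-leaf cophenetic distance equal to the merge distance. Distance
ties are broken toward the lexicographically smallest pair of member-id
sets so that rebuilt trees are bit-identical; clusters from `cut_k()` are
labelled A, B, C, ... by the leftmost leaf of each subtree in the
dendrogram layout, a deterministic stand-in for arbitrary group naming.
Newick export writes branch lengths as height differences, ordering the
children of every node by their smallest leaf label.

Fit of the tree to the input distances is diagnosed by the cophenetic
correlation (Pearson $r$ between original and tree-implied distances over
unordered pairs). It is exactly 1 on ultrametric input. On strongly
differentiated simulated collections the whole-tree $r$ is typically
0.97–0.98; per-subtree coefficients can be computed the same way but are
not comparable to any published per-cluster value without that study's
raw distances.

## Population-number heuristics: Evanno ΔK

When an external Bayesian clustering program (e.g. STRUCTURE) has been
run over a contiguous range of assumed population numbers $K$ with
replicate log-likelihoods $L(K)$, `evanno_delta_k()` computes

$$\Delta K = \frac{|\,\bar L(K+1) - 2\bar L(K) + \bar L(K-1)\,|}{\mathrm{sd}\,L(K)}$$

with the sample (n−1) standard deviation, the convention of the standard
harvester tooling. The statistic is invariant to adding a constant to all
likelihoods and to a global sign flip. The MCMC itself is out of scope:
the module consumes its summary table only, which is why at least two
replicates per $K$ and a contiguous $K$ range of length ≥ 3 are hard
preconditions.

## Minimal identification fingerprints

The unit of combination is the **locus**: one PCR yields the whole band
pattern of a marker, so a practical identification assay is a set of
markers, not of individual allele columns. For each accession the package
searches the smallest locus subset whose combined pattern differs from
every other accession: subsets are enumerated by increasing cardinality
(lexicographic within a size) up to `max_exact_size` (default 4 — at 20
loci that is at most 6,195 subsets per accession, tractable and
guaranteed minimum-size), then a greedy search adds the
most-disambiguating locus and prunes removable ones. Greedy results are
minimal (no single locus can be dropped) but not necessarily minimum;
exact-vs-greedy equality is checked on all enumerable instances in the
tests. Loci that failed to amplify for an accession are excluded from its
candidates — a failed PCR cannot serve as an identifying band — and an
accession with a complete duplicate is reported as *unresolved* rather
than erroring. Every returned profile carries a certificate: for each
other accession, one subset locus where the patterns differ.

## Cluster–phenotype association

Two complementary views connect genetic clusters to tuber phenotypes:

* `above_mean_counts()` tallies, per cluster, accessions **strictly**
  above the population mean of TPC or anthocyanin content (ties at the
  mean are measure-zero in practice and strictness is deterministic), and
  flags clusters where above-mean accessions are over-represented.
* `enrichment_test()` tests every (cluster, trait value) pair for
  over-representation with the one-sided hypergeometric test — the
  canonical exact test for category-in-cluster enrichment — with a
  permutation alternative as a cross-check. P-values are
  Benjamini–Hochberg adjusted across all pairs within a trait axis; a
  correction had to be chosen and this one is documented rather than
  implied. Probabilities are reported cluster-conditionally
  (count / cluster size).

Class-level chemistry summaries (`color_content_summary()`) report
between-class fold-ratios at one decimal and the population max/min fold
truncated to an integer, the precisions used in germplasm
characterization reports. Ordinal color–content correlations use a rank
score over the flesh vocabulary from unpigmented to strongly pigmented;
any strictly increasing re-mapping preserves the correlation signs, and
no published numeric encoding is assumed.

## The simulator: what it emulates and what it does not

`simulation_config()` defaults encode the study conditions of a large
native-potato collection: 290 accessions, 20 SSR loci with 2–13 alleles,
K = 7 latent kinship clusters of equal expected size, and tetraploid
calls as 4 i.i.d. allele draws per locus from cluster-specific frequency
vectors drawn from a symmetric Dirichlet (concentration 0.05 — strong
differentiation). Flesh color is cluster-conditional, with clusters 2 and
6 biased toward purple/pink flesh; skin color is flesh-conditional. TPC
and anthocyanin are log-normal conditional on the pigmentation class:
pigmented (red/pink/purple) means sit a factor 7 (anthocyanin) and 1.6
(TPC) above pale-class means of 20 and 4000 µg/g DW, with log-sd 1.0 and
0.5. The log-normal choice reproduces the strong right skew of genebank
anthocyanin measurements (mean several-fold above the median). With
`anthocyanidins = TRUE` the total is allocated across the five
anthocyanidins with delphinidin-dominant weights for purple flesh.

Deliberately **not** emulated: linkage between loci, stepwise mutation
realism, double reduction or any dosage model, genotyping error, and the
real (unpublished) per-cluster color frequencies of any particular
collection — the defaults are chosen for testability. Passing the
recovery and power tests therefore shows that the pipeline is correct and
well-calibrated under its own generative assumptions, not that any real
collection will cluster with ARI 1.

## Numerical and design choices

* Distance ties in UPGMA are detected at absolute tolerance 1e-12 and
  broken lexicographically; allele-frequency normalization is checked at
  1e-9.
* Report rounding is half-away-from-zero at 2 decimals (PIC tables),
  1 decimal (fold-ratios); range folds are truncated to integers.
* Degenerate inputs are first-class: all-zero loci direct the caller to
  `drop_failed_loci()`, duplicate accessions become *unresolved*
  fingerprints, constant distance vectors make the cophenetic correlation
  error rather than return NaN.
* One global RNG stream per simulated dataset, seeded once, makes
  fixtures byte-identical under a fixed seed.
* The matrix CSV format cannot carry the missing-amplification mask; a
  matrix read back from disk has an empty mask, and similarity under the
  default `"zeros"` policy is unaffected.

Validation problem sizes (the package's own choices): UPGMA is checked
against a from-scratch reference on hundreds of 5–7 leaf matrices and
against average-linkage `hclust` on larger tie-free ones; fingerprint
search against brute-force enumeration on up to 12 accessions × 6 loci;
cluster recovery on ten 290-accession simulations (adjusted Rand index at
k = 7); enrichment calibration on 500 null draws of a balanced two-cluster
design where the attainable one-sided hypergeometric level is essentially
nominal (0.04998 at α = 0.05), and planted-association power on twenty
simulated collections.

## Known limitations

* Presence-based frequencies understate diversity relative to true
  gametic frequencies; PIC values are comparable within this convention
  only.
* With strong differentiation, distinct accessions can still share a full
  21-band profile; such duplicates are detectable but not separable by
  any marker subset.
* Greedy fingerprints are not guaranteed minimum-size beyond the exact
  search cap.
* Per-subtree cophenetic coefficients depend on the within-cluster
  distance spread and are not validated against any published per-cluster
  range.
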