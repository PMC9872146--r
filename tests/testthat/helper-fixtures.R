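# fixtures built in code, plus independent oracles used across test files

# three-locus toy panel
toy_panel <- function() {
  locus_panel(tibble::tibble(
    locus = c("L1", "L2", "L3"),
    size_min = c(98, 198, 298),
    size_max = c(112, 212, 312),
    bins = list(
      tibble::tibble(label = c("100±1", "105±1", "110±1"),
                     center = c(100, 105, 110), tolerance = 1),
      tibble::tibble(label = c("200±1", "210±1"),
                     center = c(200, 210), tolerance = 1),
      tibble::tibble(label = c("300±1", "305±1", "310±1"),
                     center = c(300, 305, 310), tolerance = 1)
    )
  ))
}

# genotype table from a compact list spec: list(ACC = list(L1 = c(...), ...))
toy_genotypes <- function(spec) {
  rows <- purrr::imap_dfr(spec, function(loci, acc) {
    tibble::tibble(accession = acc, locus = names(loci), sizes = unname(loci))
  })
  genotype_table(rows)
}

# random small allele matrix via the package's own simulator (weak
# structure: one cluster, moderate Dirichlet concentration)
random_allele_matrix <- function(n_acc, n_loci, seed, alleles = c(2, 4)) {
  cfg <- simulation_config(
    n_accessions = n_acc, n_loci = n_loci, allele_range = alleles,
    n_clusters = 1, cluster_props = 1, dirichlet_alpha = 1
  )
  set.seed(seed)
  panel <- simulate_panel(cfg)
  sim <- simulate_genotypes(cfg, panel)
  binarize(sim$genotypes, panel)
}

# --- independent UPGMA oracle -------------------------------------------
# Naive reference: at every step recompute each pair of cluster distances
# from scratch as the plain mean over all original cross-pair distances
# (the defining property of UPGMA), with the same lexicographic tie-break.
# Returns the cophenetic matrix.
oracle_upgma_coph <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  set_key <- function(members) paste(sort(members), collapse = ",")
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    bestd <- Inf
    bestkey <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        key <- paste(sort(c(set_key(clusters[[i]]), set_key(clusters[[j]]))),
                     collapse = "|")
        if (dd < bestd - 1e-12 ||
            (abs(dd - bestd) <= 1e-12 && key < bestkey)) {
          best <- c(i, j)
          bestd <- dd
          bestkey <- key
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- bestd
    coph[b, a] <- bestd
    clusters[[best[1]]] <- c(a, b)
    clusters <- clusters[-best[2]]
  }
  coph
}

# random distance matrix on n leaves
random_distance <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 1)
  d <- d + t(d)
  dimnames(d) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  d
}

# --- independent fingerprint oracle -------------------------------------
# Brute-force enumeration over raw allele columns (no locus hashing):
# first unique subset by increasing cardinality, lexicographic locus order.
oracle_min_fingerprint <- function(x, acc) {
  m <- as_matrix(x)
  cmap <- column_map(x)
  loci <- sort(unique(cmap$locus))
  row_a <- m[acc, ]
  others <- setdiff(rownames(m), acc)
  subset_unique <- function(s) {
    cols <- cmap$column[cmap$locus %in% s]
    !any(vapply(others, function(o) all(m[o, cols] == row_a[cols]), logical(1)))
  }
  for (size in seq_along(loci)) {
    for (s in utils::combn(loci, size, simplify = FALSE)) {
      if (subset_unique(s)) return(s)
    }
  }
  NULL
}
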