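#' Configuration for the genebank simulator
#'
#' Defines the study conditions the synthetic module emulates: a genebank
#' of ~290 autotetraploid accessions genotyped at ~20 SSR loci carrying
#' 2--13 binned alleles each, organized in K = 7 latent kinship clusters,
#' with tuber color classes distributed cluster-specifically and pigment
#' chemistry (TPC, anthocyanin) conditional on the flesh color class.
#'
#' @param n_accessions Number of accessions (default 290).
#' @param n_loci Number of SSR loci (default 20).
#' @param allele_range Integer range of allele bins per locus (default
#'   `c(2, 13)`).
#' @param n_clusters Number of latent kinship clusters K (default 7).
#' @param cluster_props Cluster membership proportions, summing to 1
#'   (default equal).
#' @param dirichlet_alpha Dirichlet concentration of per-cluster allele
#'   frequencies; small values give strongly differentiated clusters
#'   (default 0.05).
#' @param ploidy Allele draws per locus per accession (default 4,
#'   autotetraploid; duplicates collapse to presence).
#' @param color_bias If `TRUE` (default), flesh-color distributions differ
#'   by cluster, with `pigment_clusters` biased toward purple/pink flesh;
#'   if `FALSE`, every cluster shares one color distribution (the null for
#'   enrichment testing).
#' @param pigment_clusters Indices of the clusters biased toward pigmented
#'   flesh (default: clusters 2 and 6 when K >= 6, mimicking two
#'   pigment-rich kinship groups; otherwise the last cluster).
#' @param anthocyanin_fold Mean anthocyanin fold-factor of pigmented
#'   (red/pink/purple) over pale flesh classes (default 7).
#' @param tpc_fold Mean TPC fold-factor of pigmented over pale classes
#'   (default 1.6).
#' @param tpc_base_mean Mean TPC of pale-fleshed accessions, µg GAE/g DW
#'   (default 4000).
#' @param anthocyanin_base_mean Mean anthocyanin content of pale-fleshed
#'   accessions, µg Cy3Glu/g DW (default 20).
#' @param tpc_sdlog,anthocyanin_sdlog Log-scale standard deviations of the
#'   log-normal content models (defaults 0.5 and 1.0; the larger
#'   anthocyanin spread reproduces the strong right skew of genebank
#'   anthocyanin measurements, mean well above median).
#' @param anthocyanidins If `TRUE`, also simulate the five-anthocyanidin
#'   profile (delphinidin-dominant for purple flesh).
#' @param missing_rate Per-call probability of a failed amplification
#'   (default 0).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_accessions = 290,
                              n_loci = 20,
                              allele_range = c(2, 13),
                              n_clusters = 7,
                              cluster_props = NULL,
                              dirichlet_alpha = 0.05,
                              ploidy = 4,
                              color_bias = TRUE,
                              pigment_clusters = NULL,
                              anthocyanin_fold = 7,
                              tpc_fold = 1.6,
                              tpc_base_mean = 4000,
                              anthocyanin_base_mean = 20,
                              tpc_sdlog = 0.5,
                              anthocyanin_sdlog = 1.0,
                              anthocyanidins = FALSE,
                              missing_rate = 0) {
  cluster_props <- cluster_props %||% rep(1 / n_clusters, n_clusters)
  pigment_clusters <- pigment_clusters %||%
    (if (n_clusters >= 6) c(2, 6) else n_clusters)
  stopifnot(
    n_accessions >= 2, n_loci >= 1, length(allele_range) == 2,
    allele_range[1] >= 1, allele_range[2] >= allele_range[1],
    n_clusters >= 1, length(cluster_props) == n_clusters,
    dirichlet_alpha > 0, ploidy >= 1,
    anthocyanin_fold > 0, tpc_fold > 0,
    missing_rate >= 0, missing_rate < 1
  )
  if (abs(sum(cluster_props) - 1) > 1e-8) abort("cluster_props must sum to 1")
  if (!all(pigment_clusters %in% seq_len(n_clusters))) {
    abort("pigment_clusters must index clusters 1..K")
  }
  structure(
    list(
      n_accessions = n_accessions, n_loci = n_loci,
      allele_range = as.integer(allele_range), n_clusters = n_clusters,
      cluster_props = cluster_props, dirichlet_alpha = dirichlet_alpha,
      ploidy = ploidy, color_bias = color_bias,
      pigment_clusters = pigment_clusters,
      anthocyanin_fold = anthocyanin_fold, tpc_fold = tpc_fold,
      tpc_base_mean = tpc_base_mean,
      anthocyanin_base_mean = anthocyanin_base_mean,
      tpc_sdlog = tpc_sdlog, anthocyanin_sdlog = anthocyanin_sdlog,
      anthocyanidins = anthocyanidins, missing_rate = missing_rate
    ),
    class = "simulation_config"
  )
}

#' Simulate an SSR locus panel
#'
#' Draws `n_loci` loci with allele counts uniform in the configured range.
#' Bin centers are spaced at least `2 * tolerance + 1` bp apart so bins
#' never overlap and every simulated fragment is unambiguously assignable.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed (sets the RNG once).
#' @return A [locus_panel()] with loci named `SSR01`, `SSR02`, ...
#' @export
simulate_panel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  loci <- purrr::map_dfr(seq_len(config$n_loci), function(i) {
    k_choices <- seq(config$allele_range[1], config$allele_range[2])
    k <- k_choices[sample.int(length(k_choices), 1)]
    tol <- sample(0:2, 1)
    start <- sample(80:300, 1)
    step <- 2 * tol + 1 + sample(0:2, 1)
    centers <- start + step * (seq_len(k) - 1)
    bins <- tibble(
      label = if (tol > 0) paste0(centers, "±", tol) else as.character(centers),
      center = centers, tolerance = tol
    )
    tibble(
      locus = sprintf("SSR%02d", i),
      size_min = min(centers) - tol, size_max = max(centers) + tol,
      bins = list(bins)
    )
  })
  locus_panel(loci)
}

# one Dirichlet(alpha) draw of length k
rdirichlet1 <- function(k, alpha) {
  g <- rgamma(k, shape = alpha, rate = 1)
  while (sum(g) == 0) g <- rgamma(k, shape = alpha, rate = 1)  # guard tiny alpha underflow
  g / sum(g)
}

#' Simulate tetraploid SSR genotypes with planted cluster structure
#'
#' Each cluster gets independent per-locus allele frequencies drawn from a
#' symmetric Dirichlet with concentration `dirichlet_alpha`; each accession
#' then draws `ploidy` alleles i.i.d. from its cluster's frequencies
#' (duplicates collapse to presence, dosage is not recorded). Fragment
#' sizes are emitted at bin centers.
#'
#' @param config A [simulation_config()].
#' @param panel A [locus_panel()], typically from [simulate_panel()].
#' @param seed Optional integer seed.
#' @return A list with `genotypes` (a [genotype_table()]) and `truth`, a
#'   tibble `accession`, `cluster` (integer labels 1..K) carrying the
#'   per-cluster per-locus frequency vectors as attribute
#'   `"allele_frequencies"`.
#' @export
simulate_genotypes <- function(config, panel, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"), inherits(panel, "locus_panel"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_accessions
  K <- config$n_clusters
  accessions <- sprintf("ACC%03d", seq_len(n))
  cluster <- sample(seq_len(K), n, replace = TRUE, prob = config$cluster_props)
  # guarantee every cluster is populated so the planted structure exists
  short <- setdiff(seq_len(K), unique(cluster))
  if (length(short) > 0) cluster[sample(n, length(short))] <- short

  freqs <- purrr::map(seq_len(K), function(kk) {
    purrr::map(panel$bins, function(b) {
      labels <- unique(b$label)
      setNames(rdirichlet1(length(labels), config$dirichlet_alpha), labels)
    }) |> setNames(panel$locus)
  })

  center_of <- purrr::map(panel$bins, function(b) {
    # first interval center of each allele bin label
    b_first <- b[!duplicated(b$label), ]
    setNames(b_first$center, b_first$label)
  }) |> setNames(panel$locus)

  rows <- vector("list", n * nrow(panel))
  r <- 0L
  for (a in seq_len(n)) {
    for (l in seq_len(nrow(panel))) {
      r <- r + 1L
      loc <- panel$locus[l]
      if (config$missing_rate > 0 && runif(1) < config$missing_rate) {
        rows[[r]] <- list(accession = accessions[a], locus = loc, sizes = numeric(0))
        next
      }
      f <- freqs[[cluster[a]]][[loc]]
      drawn <- sample(names(f), config$ploidy, replace = TRUE, prob = f)
      sizes <- unname(center_of[[loc]][unique(drawn)])
      rows[[r]] <- list(accession = accessions[a], locus = loc, sizes = sizes)
    }
  }
  genotypes <- genotype_table(tibble(
    accession = purrr::map_chr(rows, "accession"),
    locus = purrr::map_chr(rows, "locus"),
    sizes = purrr::map(rows, "sizes")
  ))
  truth <- tibble(accession = accessions, cluster = cluster)
  attr(truth, "allele_frequencies") <- freqs
  list(genotypes = genotypes, truth = truth)
}

# per-cluster flesh-color distributions
flesh_color_probs <- function(config, cluster_index) {
  v <- flesh_colors()
  pale <- setNames(c(0.10, 0.40, 0.12, 0.28, 0.04, 0.01, 0.03, 0.02), v)
  pigmented <- setNames(c(0.04, 0.18, 0.04, 0.09, 0.02, 0.05, 0.14, 0.44), v)
  if (!config$color_bias) return(pale)
  if (cluster_index %in% config$pigment_clusters) pigmented else pale
}

skin_color_probs <- function(flesh) {
  v <- skin_colors()
  if (flesh %in% pigmented_flesh()) {
    setNames(c(0.02, 0.05, 0.01, 0.02, 0.12, 0.10, 0.08, 0.35, 0.25), v)
  } else {
    setNames(c(0.15, 0.30, 0.05, 0.20, 0.12, 0.08, 0.04, 0.04, 0.02), v)
  }
}

#' Simulate cluster-correlated tuber phenotypes
#'
#' Flesh color is drawn from the accession's cluster-specific categorical
#' distribution; skin color from a flesh-conditional distribution;
#' secondary colors are mostly `"none"`. TPC and anthocyanin content are
#' log-normal conditional on the flesh pigmentation class: accessions with
#' red/pink/purple flesh have mean content `tpc_fold` (default 1.6) and
#' `anthocyanin_fold` (default 7) times the pale-class mean, respectively.
#' With `anthocyanidins = TRUE` the total anthocyanin is allocated across
#' the five anthocyanidins, delphinidin-dominant for purple flesh.
#'
#' @param truth Truth tibble from [simulate_genotypes()] (`accession`,
#'   `cluster`).
#' @param config A [simulation_config()].
#' @param seed Optional integer seed.
#' @return A [phenotype_table()].
#' @export
simulate_phenotypes <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  assert_columns(truth, c("accession", "cluster"), "truth")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  flesh <- vapply(truth$cluster, function(kk) {
    p <- flesh_color_probs(config, kk)
    sample(names(p), 1, prob = p)
  }, character(1))
  skin <- vapply(flesh, function(fl) {
    p <- skin_color_probs(fl)
    sample(names(p), 1, prob = p)
  }, character(1))
  sec_flesh <- ifelse(runif(n) < 0.7, "none",
                      sample(flesh_colors(), n, replace = TRUE))
  sec_skin <- ifelse(runif(n) < 0.6, "none",
                     sample(skin_colors(), n, replace = TRUE))
  pig <- flesh %in% pigmented_flesh()

  meanlog_tpc <- log(config$tpc_base_mean) - config$tpc_sdlog^2 / 2 +
    log(ifelse(pig, config$tpc_fold, 1))
  meanlog_ant <- log(config$anthocyanin_base_mean) - config$anthocyanin_sdlog^2 / 2 +
    log(ifelse(pig, config$anthocyanin_fold, 1))
  tpc <- rlnorm(n, meanlog_tpc, config$tpc_sdlog)
  anthocyanin <- rlnorm(n, meanlog_ant, config$anthocyanin_sdlog)

  out <- tibble(
    accession = truth$accession,
    skin_primary = unname(skin), skin_secondary = unname(sec_skin),
    flesh_primary = unname(flesh), flesh_secondary = unname(sec_flesh),
    tpc = tpc, anthocyanin = anthocyanin
  )
  if (config$anthocyanidins) {
    w_purple <- c(delphinidin = 0.60, cyanidin = 0.12, petunidin = 0.14,
                  peonidin = 0.04, malvidin = 0.10)
    w_other <- c(delphinidin = 0.20, cyanidin = 0.35, petunidin = 0.20,
                 peonidin = 0.10, malvidin = 0.15)
    shares <- t(vapply(seq_len(n), function(i) {
      w <- if (flesh[i] == "purple") w_purple else w_other
      g <- rgamma(5, shape = 50 * w, rate = 1)
      g / sum(g)
    }, numeric(5)))
    colnames(shares) <- anthocyanidin_names()
    out <- dplyr::bind_cols(out, as_tibble(shares * anthocyanin))
  }
  phenotype_table(out)
}

#' Simulate a complete genebank dataset
#'
#' Convenience wrapper running [simulate_panel()], [simulate_genotypes()]
#' and [simulate_phenotypes()] from a single seed (one global RNG stream).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list `panel`, `genotypes`, `truth`, `phenotypes`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1) {
  set.seed(seed)
  panel <- simulate_panel(config)
  g <- simulate_genotypes(config, panel)
  phenotypes <- simulate_phenotypes(g$truth, config)
  list(panel = panel, genotypes = g$genotypes, truth = g$truth,
       phenotypes = phenotypes)
}

#' Write a synthetic fixture set to disk
#'
#' Emits `panel.json`, `genotypes.csv`, `phenotypes.csv` and `truth.json`
#' into a directory and returns the file manifest. Re-running with the
#' same config and seed reproduces the files byte-for-byte.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return A tibble manifest (`file`, `path`) with the seed as an
#'   attribute, invisibly.
#' @export
write_fixture_set <- function(config = simulation_config(), out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory: %s", out_dir))
  sim <- simulate_dataset(config, seed = seed)
  paths <- c(
    panel = file.path(out_dir, "panel.json"),
    genotypes = file.path(out_dir, "genotypes.csv"),
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_panel(sim$panel, paths["panel"])
  write_genotype_table(sim$genotypes, paths["genotypes"])
  write_phenotypes(sim$phenotypes, paths["phenotypes"])
  jsonlite::write_json(
    list(seed = seed,
         clusters = setNames(as.list(sim$truth$cluster), sim$truth$accession)),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest <- tibble(file = names(paths), path = unname(paths))
  attr(manifest, "seed") <- seed
  invisible(manifest)
}
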