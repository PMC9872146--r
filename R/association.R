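#' Per-cluster counts of accessions above the population mean
#'
#' For a concentration trait (TPC or anthocyanin), computes the mean over
#' all accessions and tallies, per genetic cluster, the accessions strictly
#' above it. Each cluster is additionally tested for over-representation of
#' above-mean accessions (one-sided hypergeometric, BH-adjusted across
#' clusters), reproducing the "which clusters concentrate the high-content
#' genotypes" reading of a genebank characterization.
#'
#' @param phenotypes A [phenotype_table()] (or any data frame with
#'   `accession` and the trait column).
#' @param clusters A `cluster_assignment` (see [cut_k()]) or data frame
#'   with columns `accession`, `cluster` covering the phenotyped
#'   accessions.
#' @param trait `"tpc"` or `"anthocyanin"`.
#' @param alpha Significance level on the adjusted p-values.
#' @return An `above_mean_summary` tibble: `cluster`, `cluster_size`,
#'   `n_above`, `p`, `p_adj`, `significant`; attributes `trait`, `mean`
#'   (population mean) and `total_above`.
#' @export
above_mean_counts <- function(phenotypes, clusters, trait = c("tpc", "anthocyanin"),
                              alpha = 0.05) {
  trait <- match.arg(trait)
  assert_columns(phenotypes, c("accession", trait), "phenotypes")
  assert_columns(clusters, c("accession", "cluster"), "clusters")
  if (nrow(phenotypes) == 0) abort("empty phenotype input")
  joined <- dplyr::inner_join(
    tibble(accession = phenotypes$accession, value = phenotypes[[trait]]),
    tibble(accession = clusters$accession, cluster = clusters$cluster),
    by = "accession"
  )
  if (nrow(joined) == 0) abort("clusters cover none of the phenotyped accessions")
  mu <- mean(joined$value)
  joined$above <- joined$value > mu
  n_total <- nrow(joined)
  total_above <- sum(joined$above)
  out <- joined |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(
      cluster_size = dplyr::n(),
      n_above = sum(.data$above),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster)
  out$p <- phyper(out$n_above - 1, total_above, n_total - total_above,
                  out$cluster_size, lower.tail = FALSE)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- new_tibble(out, class = "above_mean_summary")
  attr(out, "trait") <- trait
  attr(out, "mean") <- mu
  attr(out, "total_above") <- total_above
  out
}

#' @export
print.above_mean_summary <- function(x, ...) {
  cat(sprintf("# Above-mean %s: population mean %.4g, %d/%d accessions above\n",
              attr(x, "trait"), attr(x, "mean"), attr(x, "total_above"),
              sum(x$cluster_size)))
  NextMethod()
}

#' Cluster-trait enrichment test
#'
#' For every combination of genetic cluster and categorical trait value
#' (e.g. a CIP color class on one color axis), tests whether accessions
#' carrying the value are over-represented in the cluster. The default is
#' the one-sided hypergeometric test (population = all clustered
#' accessions, successes = trait carriers, draws = cluster size); the
#' permutation alternative shuffles cluster labels and uses
#' `p = (1 + #{permuted count >= observed}) / (1 + n_perm)`. P-values are
#' Benjamini-Hochberg adjusted across all (cluster, value) pairs within
#' each trait axis.
#'
#' @param clusters Data frame with `accession`, `cluster`.
#' @param traits Data frame with `accession` and one or more categorical
#'   trait columns (each column is one axis, e.g. `flesh_primary`).
#' @param alpha Significance level applied to adjusted p-values.
#' @param method `"hypergeometric"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations for the permutation method.
#' @return An `ssr_enrichment` tibble with columns `axis`, `cluster`,
#'   `value`, `count`, `cluster_size`, `total`, `probability`
#'   (= count / cluster size), `p`, `p_adj`, `significant`.
#' @export
enrichment_test <- function(clusters, traits, alpha = 0.05,
                            method = c("hypergeometric", "permutation"),
                            n_perm = 10000) {
  method <- match.arg(method)
  assert_columns(clusters, c("accession", "cluster"), "clusters")
  assert_columns(traits, "accession", "traits")
  axes <- setdiff(names(traits), "accession")
  if (length(axes) == 0) abort("traits has no trait columns")
  if (length(unique(clusters$cluster)) < 2) abort("need at least 2 clusters")

  res <- purrr::map_dfr(axes, function(axis) {
    joined <- dplyr::inner_join(
      clusters[c("accession", "cluster")],
      tibble(accession = traits$accession, value = traits[[axis]]),
      by = "accession"
    )
    n_total <- nrow(joined)
    cl_sizes <- table(joined$cluster)
    val_totals <- table(joined$value)
    counts <- as.data.frame(table(cluster = joined$cluster, value = joined$value),
                            stringsAsFactors = FALSE)
    counts <- as_tibble(counts)
    names(counts)[3] <- "count"
    counts$cluster_size <- as.integer(cl_sizes[counts$cluster])
    counts$total <- as.integer(val_totals[counts$value])
    counts$probability <- counts$count / counts$cluster_size
    if (method == "hypergeometric") {
      counts$p <- phyper(counts$count - 1, counts$total,
                         n_total - counts$total, counts$cluster_size,
                         lower.tail = FALSE)
    } else {
      obs <- counts$count
      exceed <- rep(0L, nrow(counts))
      key <- paste(counts$cluster, counts$value, sep = "\x1f")
      for (b in seq_len(n_perm)) {
        perm <- sample(joined$cluster)
        t_b <- table(cluster = perm, value = joined$value)
        df_b <- as.data.frame(t_b, stringsAsFactors = FALSE)
        cnt_b <- df_b$Freq[match(key, paste(df_b$cluster, df_b$value, sep = "\x1f"))]
        exceed <- exceed + as.integer(cnt_b >= obs)
      }
      counts$p <- (1 + exceed) / (1 + n_perm)
    }
    counts$p_adj <- p.adjust(counts$p, method = "BH")
    dplyr::bind_cols(tibble(axis = axis), counts)
  })
  res$significant <- res$p_adj < alpha
  res <- dplyr::arrange(res, .data$axis, .data$cluster, .data$value)
  new_tibble(res, class = "ssr_enrichment")
}

#' @export
print.ssr_enrichment <- function(x, ...) {
  cat(sprintf("# Cluster-trait enrichment: %d axis/axes, %d significant of %d tests\n",
              length(unique(x$axis)), sum(x$significant), nrow(x)))
  NextMethod()
}

#' Content summaries by tuber color class
#'
#' Groups accessions by a flesh-color axis and reports per-class counts and
#' mean TPC / anthocyanin content, pairwise between-class fold-ratios
#' (reported at 1-decimal precision, the convention of germplasm
#' characterization reports), and the population-wide max/min
#' fold-difference for each trait truncated to an integer.
#'
#' @param phenotypes A [phenotype_table()].
#' @param group_by `"flesh_primary"` or `"flesh_secondary"`.
#' @return A `color_content_summary` tibble (`color`, `n`, `mean_tpc`,
#'   `mean_anthocyanin`). Attribute `"ratios"` holds the pairwise
#'   fold-ratio tibble; attribute `"range_fold"` the named vector of
#'   truncated max/min folds (`tpc`, `anthocyanin`).
#' @export
color_content_summary <- function(phenotypes,
                                  group_by = c("flesh_primary", "flesh_secondary")) {
  group_by <- match.arg(group_by)
  assert_columns(phenotypes, c(group_by, "tpc", "anthocyanin"), "phenotypes")
  if (nrow(phenotypes) == 0) abort("empty phenotype input")
  cls <- phenotypes |>
    dplyr::group_by(color = .data[[group_by]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_tpc = mean(.data$tpc),
      mean_anthocyanin = mean(.data$anthocyanin),
      .groups = "drop"
    )
  pairs <- tidyr::expand_grid(color_a = cls$color, color_b = cls$color)
  pairs <- dplyr::left_join(pairs, cls, by = c("color_a" = "color"))
  pairs <- dplyr::left_join(pairs, cls, by = c("color_b" = "color"),
                            suffix = c("_a", "_b"))
  ratios <- tibble(
    color_a = pairs$color_a,
    color_b = pairs$color_b,
    tpc_ratio = round_half_up(pairs$mean_tpc_a / pairs$mean_tpc_b, 1),
    anthocyanin_ratio = round_half_up(pairs$mean_anthocyanin_a / pairs$mean_anthocyanin_b, 1)
  )
  range_fold <- c(
    tpc = if (min(phenotypes$tpc) > 0) floor(max(phenotypes$tpc) / min(phenotypes$tpc)) else NA_real_,
    anthocyanin = if (min(phenotypes$anthocyanin) > 0) {
      floor(max(phenotypes$anthocyanin) / min(phenotypes$anthocyanin))
    } else NA_real_
  )
  out <- new_tibble(cls, class = "color_content_summary")
  attr(out, "ratios") <- ratios
  attr(out, "range_fold") <- range_fold
  attr(out, "group_by") <- group_by
  out
}

#' @rdname color_content_summary
#' @param x A `color_content_summary`.
#' @export
fold_ratios <- function(x) {
  stopifnot(inherits(x, "color_content_summary"))
  attr(x, "ratios")
}

#' @rdname color_content_summary
#' @export
range_fold <- function(x) {
  stopifnot(inherits(x, "color_content_summary"))
  attr(x, "range_fold")
}

#' Default ordinal CIP-style flesh pigmentation score
#'
#' Orders the flesh color vocabulary from unpigmented to strongly
#' anthocyanin-pigmented and assigns ranks 1..8. The exact published CIP
#' encoding is not standardized in print; any strictly increasing
#' re-mapping leaves correlation signs unchanged.
#'
#' @return Named numeric vector over [flesh_colors()].
#' @export
flesh_score_map <- function() {
  setNames(seq_along(flesh_colors()), flesh_colors())
}

#' Correlation between pigment content and flesh color score
#'
#' Pearson correlations between TPC and the ordinal flesh pigmentation
#' score, anthocyanin content and the score, and TPC and anthocyanin
#' content.
#'
#' @param phenotypes A [phenotype_table()].
#' @param score_map Named numeric vector mapping flesh colors to ordinal
#'   scores; defaults to [flesh_score_map()].
#' @return A tibble with columns `pair`, `r`.
#' @export
content_color_correlation <- function(phenotypes, score_map = flesh_score_map()) {
  assert_columns(phenotypes, c("flesh_primary", "tpc", "anthocyanin"), "phenotypes")
  score <- unname(score_map[phenotypes$flesh_primary])
  if (anyNA(score)) abort("score_map does not cover all flesh colors present")
  for (v in list(score, phenotypes$tpc, phenotypes$anthocyanin)) {
    if (sd(v) == 0) abort("correlation undefined: constant vector")
  }
  tibble(
    pair = c("tpc~flesh_score", "anthocyanin~flesh_score", "tpc~anthocyanin"),
    r = c(
      cor(phenotypes$tpc, score),
      cor(phenotypes$anthocyanin, score),
      cor(phenotypes$tpc, phenotypes$anthocyanin)
    )
  )
}
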