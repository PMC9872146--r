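# broom-style tidy()/glance() methods for the package's result objects

#' @method tidy ssr_diversity
#' @export
tidy.ssr_diversity <- function(x, ...) as_tibble(x)

#' Panel-level aggregates of a diversity summary
#'
#' @param x An `ssr_diversity` from [diversity_summary()].
#' @param ... Unused.
#' @return One-row tibble: locus count, mean/min/max PIC, mean/min/max
#'   alleles per locus, total allele count (allele aggregates are `NA` when
#'   allele counts were not supplied).
#' @method glance ssr_diversity
#' @export
glance.ssr_diversity <- function(x, ...) {
  has_n <- !anyNA(x$n_alleles)
  tibble(
    n_loci = nrow(x),
    mean_pic = mean(x$pic),
    min_pic = min(x$pic),
    max_pic = max(x$pic),
    mean_alleles = if (has_n) mean(x$n_alleles) else NA_real_,
    min_alleles = if (has_n) min(x$n_alleles) else NA_integer_,
    max_alleles = if (has_n) max(x$n_alleles) else NA_integer_,
    total_alleles = if (has_n) sum(x$n_alleles) else NA_integer_
  )
}

#' Merge table of a UPGMA dendrogram
#'
#' @param x An `ssr_dendrogram` from [upgma()].
#' @param ... Unused.
#' @return A tibble with one row per merge: `step`, `merge1`, `merge2`
#'   (hclust codes: negative = leaf index, positive = earlier step),
#'   `distance` (merge distance) and `height` (node height =
#'   distance / 2).
#' @method tidy ssr_dendrogram
#' @export
tidy.ssr_dendrogram <- function(x, ...) {
  tibble(
    step = seq_along(x$height),
    merge1 = x$merge[, 1], merge2 = x$merge[, 2],
    distance = x$height, height = x$height / 2
  )
}

#' @method glance ssr_dendrogram
#' @export
glance.ssr_dendrogram <- function(x, ...) {
  tibble(
    n_leaves = length(x$labels),
    n_merges = length(x$height),
    root_height = max(x$height) / 2
  )
}

#' @method tidy ssr_enrichment
#' @export
tidy.ssr_enrichment <- function(x, ...) as_tibble(x)

#' @method glance ssr_enrichment
#' @export
glance.ssr_enrichment <- function(x, ...) {
  tibble(
    n_axes = length(unique(x$axis)),
    n_tests = nrow(x),
    n_significant = sum(x$significant)
  )
}

#' @method tidy above_mean_summary
#' @export
tidy.above_mean_summary <- function(x, ...) as_tibble(x)

#' @method glance above_mean_summary
#' @export
glance.above_mean_summary <- function(x, ...) {
  tibble(
    trait = attr(x, "trait"),
    population_mean = attr(x, "mean"),
    total_above = attr(x, "total_above"),
    n_clusters = nrow(x)
  )
}

#' @method tidy fingerprint_report
#' @export
tidy.fingerprint_report <- function(x, ...) as_tibble(x)

#' @method glance fingerprint_report
#' @export
glance.fingerprint_report <- function(x, ...) {
  tibble(
    n_accessions = nrow(x),
    n_unresolved = sum(!x$resolved),
    n_exact = sum(x$mode == "exact", na.rm = TRUE),
    n_greedy = sum(x$mode == "greedy", na.rm = TRUE),
    median_size = stats::median(x$n_loci, na.rm = TRUE),
    max_size = suppressWarnings(max(x$n_loci, na.rm = TRUE))
  )
}

#' @method glance color_content_summary
#' @export
glance.color_content_summary <- function(x, ...) {
  rf <- range_fold(x)
  tibble(
    group_by = attr(x, "group_by"),
    n_classes = nrow(x),
    tpc_range_fold = rf[["tpc"]],
    anthocyanin_range_fold = rf[["anthocyanin"]]
  )
}
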