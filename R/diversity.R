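#' Allele frequencies at one locus
#'
#' Frequencies are computed from band presence counts on the binary allele
#' matrix: f_i = (accessions carrying allele i) / (total presence count over
#' all alleles of the locus). With dosage unobserved in tetraploids, these
#' presence-based frequencies are the quantity entering [pic()].
#'
#' @param x An `allele_matrix` (see [binarize()]).
#' @param locus Locus name.
#' @return Named numeric vector of frequencies over the locus's allele-bin
#'   labels, summing to 1. Alleles observed in no accession get frequency 0.
#' @export
allele_frequencies <- function(x, locus) {
  stopifnot(inherits(x, "allele_matrix"))
  cmap <- column_map(x)
  cols <- cmap$column[cmap$locus == locus]
  if (length(cols) == 0) abort(sprintf("unknown locus: %s", locus))
  counts <- colSums(as_matrix(x)[, cols, drop = FALSE])
  total <- sum(counts)
  if (total == 0) {
    abort(sprintf(
      "locus %s has no amplified allele in any accession; run drop_failed_loci() first",
      locus
    ))
  }
  f <- counts / total
  names(f) <- cmap$label[cmap$locus == locus]
  f
}

#' Polymorphism information content
#'
#' PIC = 1 - sum(f_i^2) over the allele frequencies f_i of a locus. It lies
#' in `[0, 1 - 1/k]` for k alleles: 0 for a monomorphic locus, approaching 1
#' as many alleles occur at even frequency (high discriminatory power).
#'
#' @param frequencies Numeric vector of allele frequencies summing to 1
#'   (tolerance 1e-9).
#' @return The PIC value.
#' @examples
#' pic(c(0.5, 0.5)) # 0.5
#' pic(rep(1 / 13, 13)) # 1 - 1/13
#' @export
pic <- function(frequencies) {
  stopifnot(is.numeric(frequencies), length(frequencies) >= 1)
  if (any(frequencies < 0)) abort("allele frequencies must be non-negative")
  if (abs(sum(frequencies) - 1) > 1e-9) {
    abort(sprintf("allele frequencies must sum to 1 (got %.12g)", sum(frequencies)))
  }
  1 - sum(frequencies^2)
}

#' Per-locus and panel-level diversity summary
#'
#' Computes, per locus, the number of observed alleles and the PIC, plus
#' panel aggregates (mean/min/max PIC, mean/min/max alleles per locus,
#' total allele count) retrievable with [glance()]. Two inputs are
#' supported: a binary `allele_matrix`, from which frequencies are counted;
#' or a data frame already holding per-locus `pic` (and optionally
#' `n_alleles`) values -- e.g. a published panel table -- whose aggregates
#' are then reproduced directly.
#'
#' @param x An `allele_matrix`, or a data frame with columns `locus`, `pic`
#'   and optionally `n_alleles` (a [reference_panel()] works directly).
#' @param ... Unused.
#' @return An `ssr_diversity` tibble with columns `locus`, `n_alleles`
#'   (`NA` if unknown), `pic`.
#' @export
diversity_summary <- function(x, ...) UseMethod("diversity_summary")

#' @rdname diversity_summary
#' @export
diversity_summary.allele_matrix <- function(x, ...) {
  if (ncol(x) <= 1) abort("empty allele matrix")
  loci <- matrix_loci(x)
  rows <- purrr::map_dfr(loci, function(loc) {
    f <- allele_frequencies(x, loc)
    f <- f[f > 0]
    tibble(locus = loc, n_alleles = length(f), pic = pic(f))
  })
  new_tibble(rows, class = "ssr_diversity")
}

#' @rdname diversity_summary
#' @export
diversity_summary.locus_panel <- function(x, ...) {
  assert_columns(x, "pic", "panel for diversity_summary()")
  diversity_summary(tibble(
    locus = x$locus,
    n_alleles = n_alleles_per_locus(x)$n_alleles,
    pic = x$pic
  ))
}

#' @rdname diversity_summary
#' @export
diversity_summary.data.frame <- function(x, ...) {
  assert_columns(x, c("locus", "pic"), "diversity table")
  if (nrow(x) == 0) abort("empty diversity table")
  out <- tibble(
    locus = x$locus,
    n_alleles = if ("n_alleles" %in% names(x)) as.integer(x$n_alleles) else NA_integer_,
    pic = as.numeric(x$pic)
  )
  new_tibble(out, class = "ssr_diversity")
}

#' @export
print.ssr_diversity <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("# SSR diversity: %d loci, mean PIC %.2f (range %.2f-%.2f)\n",
              g$n_loci, g$mean_pic, g$min_pic, g$max_pic))
  NextMethod()
}

#' Evanno delta-K from STRUCTURE-style log-likelihoods
#'
#' Summarizes replicate log-likelihood runs over a contiguous range of K
#' (assumed number of populations) with the Evanno second-difference
#' statistic: delta_K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| /
#' sd L(K), using the sample (n-1) standard deviation across replicates.
#' Endpoint K values have no second difference and get `NA`.
#'
#' @param table Data frame with columns `K` (integer), `replicate`, `lnP`
#'   (log-likelihood of the data for that run).
#' @return A tibble with one row per K: `K`, `n_reps`, `mean_lnp`,
#'   `sd_lnp`, `delta_k` (`NA` at the two endpoints). The supported K with
#'   the largest delta-K is the usual choice for the number of populations.
#' @examples
#' tbl <- tidyr::expand_grid(K = 1:3, replicate = 1:2)
#' tbl$lnP <- c(-101, -99, -81, -79, -76, -74)
#' evanno_delta_k(tbl)
#' @export
evanno_delta_k <- function(table) {
  assert_columns(table, c("K", "replicate", "lnP"), "likelihood table")
  ks <- sort(unique(table$K))
  if (length(ks) < 3) abort("delta-K needs at least 3 contiguous K values")
  if (!all(diff(ks) == 1)) abort("K values must be contiguous")
  s <- table |>
    dplyr::group_by(K = .data$K) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      mean_lnp = mean(.data$lnP),
      sd_lnp = sd(.data$lnP),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$K)
  if (any(s$n_reps < 2)) {
    abort("every K needs at least 2 replicates for a defined sd")
  }
  interior <- seq(2, nrow(s) - 1)
  if (any(s$sd_lnp[interior] == 0)) {
    abort("zero sd of lnP at an interior K: replicates are degenerate")
  }
  d2 <- abs(s$mean_lnp[interior + 1] - 2 * s$mean_lnp[interior] + s$mean_lnp[interior - 1])
  s$delta_k <- NA_real_
  s$delta_k[interior] <- d2 / s$sd_lnp[interior]
  s
}
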