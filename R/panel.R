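#' Construct an SSR locus panel
#'
#' A locus panel describes, for each SSR marker, the expected fragment-size
#' range and the set of allele bins into which observed fragment sizes are
#' classified. Each bin is an interval `center ± tolerance` (tolerance 0 for
#' a bare size); a bin may hold several intervals that all map to one allele
#' label, the convention used when a published panel lists size alternatives
#' ("196±2 or 199") that count as a single allele.
#'
#' @param loci A data frame with columns `locus` (unique marker names),
#'   `size_min`, `size_max` (fragment-size range in bp) and `bins`, a
#'   list-column where each element is a data frame with columns `label`,
#'   `center`, `tolerance` (one row per interval; rows sharing a `label`
#'   belong to one allele bin). Optional extra columns (e.g. a reference
#'   `pic`) are kept.
#' @return A `locus_panel` tibble (one row per locus).
#' @examples
#' bins <- tibble::tibble(
#'   label = c("190±2", "200±2", "203"),
#'   center = c(190, 200, 203), tolerance = c(2, 2, 0)
#' )
#' locus_panel(tibble::tibble(
#'   locus = "STM1049", size_min = 188, size_max = 203, bins = list(bins)
#' ))
#' @seealso [assign_bin()], [read_panel()], [reference_panel()]
#' @export
locus_panel <- function(loci) {
  assert_columns(loci, c("locus", "size_min", "size_max", "bins"), "locus panel")
  loci <- as_tibble(loci)
  if (anyDuplicated(loci$locus) > 0) {
    abort("locus names must be unique in a panel")
  }
  if (nrow(loci) == 0) abort("a panel needs at least one locus")
  for (i in seq_len(nrow(loci))) {
    b <- loci$bins[[i]]
    assert_columns(b, c("label", "center", "tolerance"),
                   sprintf("bins of locus %s", loci$locus[i]))
    b <- as_tibble(b)
    if (nrow(b) == 0) abort(sprintf("locus %s has no allele bins", loci$locus[i]))
    if (any(b$center <= 0)) abort(sprintf("locus %s: bin centers must be > 0", loci$locus[i]))
    if (any(b$tolerance < 0)) abort(sprintf("locus %s: tolerances must be >= 0", loci$locus[i]))
    out_of_range <- b$center < loci$size_min[i] | b$center > loci$size_max[i]
    if (any(out_of_range)) {
      abort(sprintf(
        "locus %s: bin center(s) %s outside size range [%g, %g]",
        loci$locus[i], paste(b$center[out_of_range], collapse = ", "),
        loci$size_min[i], loci$size_max[i]
      ))
    }
    loci$bins[[i]] <- b
  }
  new_tibble(loci, class = "locus_panel")
}

#' @export
print.locus_panel <- function(x, ...) {
  cat(sprintf("# SSR locus panel: %d loci, %d allele bins\n",
              nrow(x), sum(n_alleles_per_locus(x)$n_alleles)))
  NextMethod()
}

#' Allele-bin labels and counts of a panel
#'
#' `bin_labels()` lists every allele bin of a panel as one row per bin
#' (alternative intervals sharing a label are collapsed);
#' `n_alleles_per_locus()` counts distinct allele bins per locus.
#'
#' @param panel A [locus_panel()].
#' @return A tibble; for `bin_labels()` with columns `locus`, `label`, for
#'   `n_alleles_per_locus()` with columns `locus`, `n_alleles`.
#' @export
bin_labels <- function(panel) {
  stopifnot(inherits(panel, "locus_panel"))
  purrr::map2_dfr(panel$locus, panel$bins, function(loc, b) {
    tibble(locus = loc, label = unique(b$label))
  })
}

#' @rdname bin_labels
#' @export
n_alleles_per_locus <- function(panel) {
  stopifnot(inherits(panel, "locus_panel"))
  tibble(
    locus = panel$locus,
    n_alleles = purrr::map_int(panel$bins, ~ length(unique(.x$label)))
  )
}

#' Assign an observed fragment size to an allele bin
#'
#' A size falls in a bin if it lies inside any of the bin's intervals
#' `[center - tolerance, center + tolerance]`. When several bins contain the
#' size, the bin whose nearest interval center is closest wins; an exact
#' distance tie is broken toward the lower center. A size contained in no
#' interval is unassigned (`NA`), which is a value, not an error: strictness
#' is decided by the caller (see [binarize()]).
#'
#' @param size Numeric vector of fragment sizes (bp), all positive.
#' @param locus_bins Data frame of bin intervals for one locus, as stored in
#'   the `bins` list-column of a [locus_panel()].
#' @return Character vector of bin labels, `NA` where unassigned.
#' @examples
#' bins <- tibble::tibble(
#'   label = c("190±2", "200±2", "203"),
#'   center = c(190, 200, 203), tolerance = c(2, 2, 0)
#' )
#' assign_bin(c(191, 203, 195), bins)
#' @export
assign_bin <- function(size, locus_bins) {
  stopifnot(is.numeric(size))
  if (any(size <= 0)) abort("fragment sizes must be positive")
  vapply(size, function(s) {
    hit <- abs(s - locus_bins$center) <= locus_bins$tolerance
    if (!any(hit)) return(NA_character_)
    cand <- locus_bins[hit, ]
    d <- abs(s - cand$center)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(cand$center[best])]
    cand$label[best]
  }, character(1))
}

# panel row lookup; errors on unknown locus
panel_locus <- function(panel, locus) {
  i <- match(locus, panel$locus)
  if (is.na(i)) abort(sprintf("unknown locus: %s", locus))
  panel[i, ]
}

#' Read and write locus panels as JSON
#'
#' The on-disk schema is a JSON array of loci, each
#' `{name, size_range: [min, max], bins: [{label, intervals: [{center,
#' tolerance}, ...]}, ...]}` with optional extra per-locus fields (`pic`)
#' preserved. `write_panel()` then `read_panel()` round-trips exactly.
#'
#' @param path File path of the panel JSON.
#' @param panel A [locus_panel()].
#' @return `read_panel()` returns a `locus_panel`; `write_panel()` invisibly
#'   returns `path`.
#' @export
read_panel <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  loci <- purrr::map_dfr(raw, function(l) {
    bins <- purrr::map_dfr(l$bins, function(b) {
      tibble(
        label = b$label,
        center = purrr::map_dbl(b$intervals, "center"),
        tolerance = purrr::map_dbl(b$intervals, "tolerance")
      )
    })
    row <- tibble(
      locus = l$name,
      size_min = l$size_range[[1]],
      size_max = l$size_range[[2]],
      bins = list(bins)
    )
    if (!is.null(l$pic)) row$pic <- l$pic
    row
  })
  locus_panel(loci)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "locus_panel"))
  out <- purrr::pmap(panel, function(locus, size_min, size_max, bins, ...) {
    extra <- list(...)
    by_label <- split(bins, factor(bins$label, levels = unique(bins$label)))
    l <- list(
      name = locus,
      size_range = c(size_min, size_max),
      bins = purrr::map(by_label, function(b) {
        list(
          label = b$label[1],
          intervals = purrr::map2(b$center, b$tolerance,
                                  ~ list(center = .x, tolerance = .y))
        )
      }) |> unname()
    )
    if (!is.null(extra$pic) && !is.na(extra$pic)) l$pic <- extra$pic
    l
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bundled 20-locus potato SSR reference panel
#'
#' The widely used potato genotyping SSR panel with published allele size
#' bins and reference PIC values, as applied to the 290-accession Chilotanum
#' native-potato genebank collection. Two markers of the original 22-marker
#' set (STM1106, STM2013) amplified no product in that collection and are
#' not part of the panel. The `pic` column carries the published per-locus
#' polymorphism information content, usable with [diversity_summary()] to
#' reproduce panel-level aggregates.
#'
#' @return A [locus_panel()] with 20 loci and a `pic` column.
#' @examples
#' panel <- reference_panel()
#' n_alleles_per_locus(panel)
#' @export
reference_panel <- function() {
  read_panel(system.file("extdata", "panel.json", package = "ssrdiv", mustWork = TRUE))
}
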