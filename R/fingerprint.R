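# Minimal unique SSR fingerprints.
#
# The unit of combination is the locus: a PCR with one primer pair yields
# the whole band pattern of that locus, so a fingerprint is a set of
# markers, not of individual allele columns. Internally each accession's
# band pattern at each locus is hashed to an integer code; two accessions
# agree on a locus subset iff their codes agree on every locus of the
# subset.

# integer code per (accession, locus) pattern; loci missing for an
# accession are coded NA so a failed PCR never serves as evidence
locus_codes <- function(x) {
  cmap <- column_map(x)
  m <- as_matrix(x)
  loci <- unique(cmap$locus)
  codes <- matrix(NA_integer_, nrow(m), length(loci),
                  dimnames = list(rownames(m), loci))
  for (loc in loci) {
    cols <- cmap$column[cmap$locus == loc]
    pat <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    codes[, loc] <- match(pat, unique(pat))
  }
  miss <- missing_mask(x)
  if (nrow(miss) > 0) {
    codes[cbind(match(miss$accession, rownames(m)), match(miss$locus, loci))] <- NA_integer_
  }
  codes
}

# logical (others x loci) matrix: TRUE where the other accession is NOT
# distinguishable from `acc` at that locus. NA codes on either side count
# as "not distinguishing" (a failed PCR cannot prove a difference).
equal_matrix <- function(codes, acc) {
  others <- setdiff(rownames(codes), acc)
  eq <- codes[others, , drop = FALSE] ==
    matrix(codes[acc, ], length(others), ncol(codes), byrow = TRUE)
  eq[is.na(eq)] <- TRUE
  rownames(eq) <- others
  eq
}

# others equal to `acc` on every locus of `subset`
matching_others <- function(codes, acc, subset, eq = equal_matrix(codes, acc)) {
  rownames(eq)[rowSums(!eq[, subset, drop = FALSE]) == 0]
}

#' Test uniqueness of a locus subset for one accession
#'
#' An accession is uniquely identified by a locus subset when no other
#' accession shows an identical 0/1 band pattern over all allele columns of
#' those loci. When unique, a certificate is returned: for every other
#' accession, one locus of the subset at which the band patterns differ.
#'
#' @param x An `allele_matrix`.
#' @param accession Accession id.
#' @param locus_subset Non-empty character vector of locus names.
#' @return A list with `unique` (logical), `matches` (accessions sharing
#'   the restricted profile, empty when unique) and `certificate` (named
#'   character vector, other accession -> distinguishing locus; `NULL`
#'   unless unique).
#' @export
is_unique <- function(x, accession, locus_subset) {
  stopifnot(inherits(x, "allele_matrix"), length(locus_subset) >= 1)
  if (!accession %in% x$accession) abort(sprintf("unknown accession: %s", accession))
  unknown <- setdiff(locus_subset, matrix_loci(x))
  if (length(unknown) > 0) {
    abort(sprintf("unknown locus/loci: %s", paste(unknown, collapse = ", ")))
  }
  codes <- locus_codes(x)
  same <- matching_others(codes, accession, locus_subset)
  if (length(same) > 0) {
    return(list(unique = FALSE, matches = same, certificate = NULL))
  }
  others <- setdiff(rownames(codes), accession)
  cert <- vapply(others, function(o) {
    diff <- locus_subset[
      !is.na(codes[accession, locus_subset]) & !is.na(codes[o, locus_subset]) &
        codes[accession, locus_subset] != codes[o, locus_subset]
    ]
    diff[1]
  }, character(1))
  list(unique = TRUE, matches = character(0), certificate = cert)
}

# core search over precomputed codes; returns list(loci, mode) or NULL when
# the accession is indistinguishable from a duplicate
search_fingerprint <- function(codes, acc, max_exact_size) {
  cand <- sort(colnames(codes)[!is.na(codes[acc, ])])
  if (length(cand) == 0) return(NULL)
  eq <- equal_matrix(codes, acc)
  if (any(rowSums(!eq[, cand, drop = FALSE]) == 0)) return(NULL)  # duplicate row

  # exact: subsets by increasing cardinality, lexicographic within a size
  neq <- !eq
  for (size in seq_len(min(max_exact_size, length(cand)))) {
    subsets <- combn(cand, size, simplify = FALSE)
    for (s in subsets) {
      if (all(rowSums(neq[, s, drop = FALSE]) > 0)) {
        return(list(loci = s, mode = "exact"))
      }
    }
  }

  # greedy fallback: add the locus separating the most remaining
  # confusable accessions (lexicographic tie-break), then prune
  confusable <- rownames(eq)
  chosen <- character(0)
  remaining <- cand
  while (length(confusable) > 0 && length(remaining) > 0) {
    gains <- colSums(neq[confusable, remaining, drop = FALSE])
    best <- remaining[gains == max(gains)][1]  # remaining is sorted
    if (gains[best] == 0) break
    chosen <- c(chosen, best)
    confusable <- confusable[eq[confusable, best]]
    remaining <- setdiff(remaining, best)
  }
  if (length(confusable) > 0) return(NULL)
  for (l in chosen) {
    trial <- setdiff(chosen, l)
    if (length(trial) > 0 && all(rowSums(neq[, trial, drop = FALSE]) > 0)) {
      chosen <- trial
    }
  }
  list(loci = sort(chosen), mode = "greedy")
}

#' Minimal unique SSR fingerprint for one accession
#'
#' Searches for the smallest set of loci whose combined band profile
#' distinguishes the accession from every other one in the matrix. Subsets
#' are enumerated by increasing cardinality (lexicographic locus order
#' within a size) up to `max_exact_size`; beyond that a greedy search adds
#' the most-disambiguating locus at each step and then prunes removable
#' loci. Exact-mode results are guaranteed minimum-size; greedy results are
#' minimal (no single locus can be dropped) but not necessarily minimum.
#' Loci that failed to amplify for the accession are excluded from its
#' candidate subsets.
#'
#' @param x An `allele_matrix`.
#' @param accession Accession id.
#' @param max_exact_size Largest subset cardinality searched exhaustively
#'   before falling back to greedy (default 4; 0 forces a pure greedy
#'   search).
#' @return A `fingerprint_profile` list: `accession`, `loci`, `mode`
#'   (`"exact"` or `"greedy"`), `profile` (the 0/1 pattern restricted to
#'   those loci) and `certificate`; or a profile with `resolved = FALSE`
#'   and empty loci when the accession has an exact duplicate.
#' @export
minimal_fingerprint <- function(x, accession, max_exact_size = 4) {
  stopifnot(inherits(x, "allele_matrix"))
  if (!accession %in% x$accession) abort(sprintf("unknown accession: %s", accession))
  codes <- locus_codes(x)
  fingerprint_from_codes(x, codes, accession, max_exact_size)
}

fingerprint_from_codes <- function(x, codes, accession, max_exact_size) {
  found <- search_fingerprint(codes, accession, max_exact_size)
  if (is.null(found)) {
    return(structure(
      list(accession = accession, loci = character(0), mode = NA_character_,
           resolved = FALSE, profile = NULL, certificate = NULL),
      class = "fingerprint_profile"
    ))
  }
  cmap <- column_map(x)
  cols <- cmap$column[cmap$locus %in% found$loci]
  profile <- as_matrix(x)[accession, cols]
  cert <- is_unique(x, accession, found$loci)$certificate
  structure(
    list(accession = accession, loci = found$loci, mode = found$mode,
         resolved = TRUE, profile = profile, certificate = cert),
    class = "fingerprint_profile"
  )
}

#' @export
print.fingerprint_profile <- function(x, ...) {
  if (!x$resolved) {
    cat(sprintf("# %s: unresolved (indistinguishable from a duplicate)\n", x$accession))
  } else {
    cat(sprintf("# %s: %d-locus %s fingerprint {%s}\n",
                x$accession, length(x$loci), x$mode, paste(x$loci, collapse = ", ")))
  }
  invisible(x)
}

#' Minimal fingerprints for every accession
#'
#' Runs [minimal_fingerprint()] for each accession and summarizes the
#' result: subset-size distribution and per-locus usage counts, which
#' identify the panel's most widely informative markers.
#'
#' @param x An `allele_matrix` with at least 2 accessions.
#' @param max_exact_size Passed to [minimal_fingerprint()].
#' @return A `fingerprint_report` tibble with one row per accession:
#'   `accession`, `resolved`, `mode`, `n_loci`, `loci` (list-column).
#'   Attribute `"locus_usage"` holds a tibble of loci ranked by how many
#'   fingerprints use them.
#' @export
fingerprint_all <- function(x, max_exact_size = 4) {
  stopifnot(inherits(x, "allele_matrix"))
  if (nrow(x) < 2) abort("need at least 2 accessions")
  codes <- locus_codes(x)
  profiles <- purrr::map(x$accession, function(acc) {
    fingerprint_from_codes(x, codes, acc, max_exact_size)
  })
  report <- purrr::map_dfr(profiles, function(p) {
    tibble(
      accession = p$accession, resolved = p$resolved, mode = p$mode,
      n_loci = if (p$resolved) length(p$loci) else NA_integer_,
      loci = list(p$loci)
    )
  })
  usage <- report |>
    dplyr::filter(.data$resolved) |>
    tidyr::unnest("loci") |>
    dplyr::count(locus = .data$loci, name = "n_fingerprints") |>
    dplyr::arrange(dplyr::desc(.data$n_fingerprints), .data$locus)
  report <- new_tibble(report, class = "fingerprint_report")
  attr(report, "locus_usage") <- usage
  report
}

#' @rdname fingerprint_all
#' @param report A `fingerprint_report`.
#' @export
locus_usage <- function(report) {
  stopifnot(inherits(report, "fingerprint_report"))
  attr(report, "locus_usage")
}

#' @export
print.fingerprint_report <- function(x, ...) {
  n_unres <- sum(!x$resolved)
  cat(sprintf("# Fingerprint report: %d accessions, %d unresolved; median subset size %s\n",
              nrow(x), n_unres,
              format(stats::median(x$n_loci, na.rm = TRUE))))
  NextMethod()
}
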