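#' CIP tuber color vocabularies
#'
#' Fixed category sets for tuber skin and flesh coloration under the
#' International Potato Center (CIP) characterization scale: nine skin and
#' eight flesh categories. Secondary colors additionally allow `"none"`
#' (no secondary coloration); primary colors do not.
#'
#' @param secondary If `TRUE`, include `"none"`.
#' @return Character vector of permitted category names (lower case).
#' @export
skin_colors <- function(secondary = FALSE) {
  v <- c("white cream", "yellow", "orange", "brown", "pink", "red",
         "deep pink", "purple", "blackish")
  if (secondary) c(v, "none") else v
}

#' @rdname skin_colors
#' @export
flesh_colors <- function(secondary = FALSE) {
  v <- c("white", "cream", "light yellow", "yellow", "intense yellow",
         "red", "pink", "purple")
  if (secondary) c(v, "none") else v
}

# flesh categories counted as anthocyanin-pigmented
pigmented_flesh <- function() c("red", "pink", "purple")

anthocyanidin_names <- function() {
  c("delphinidin", "cyanidin", "petunidin", "peonidin", "malvidin")
}

match_vocab <- function(x, vocab, field) {
  idx <- match(tolower(trimws(x)), vocab)
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    abort(sprintf(
      "%s: unknown color token(s) %s; permitted: %s",
      field, paste(shQuote(bad), collapse = ", "), paste(vocab, collapse = ", ")
    ))
  }
  vocab[idx]
}

#' Construct a phenotype table
#'
#' Per-accession tuber phenotype records: CIP primary/secondary skin and
#' flesh colors, total phenolic content (TPC, µg gallic-acid equivalents
#' per g dry weight) and total anthocyanin content (µg cyanidin-3-glucoside
#' equivalents per g dry weight), with an optional per-anthocyanidin
#' profile (delphinidin, cyanidin, petunidin, peonidin, malvidin, µg/g DW).
#'
#' Color strings are matched case-insensitively against the fixed CIP
#' vocabularies ([skin_colors()], [flesh_colors()]) and stored lower-case.
#'
#' @param records Data frame with columns `accession`, `skin_primary`,
#'   `skin_secondary`, `flesh_primary`, `flesh_secondary`, `tpc`,
#'   `anthocyanin`, optionally the five anthocyanidin columns.
#' @return A `phenotype_table` tibble.
#' @export
phenotype_table <- function(records) {
  required <- c("accession", "skin_primary", "skin_secondary",
                "flesh_primary", "flesh_secondary", "tpc", "anthocyanin")
  assert_columns(records, required, "phenotype table")
  x <- as_tibble(records)
  if (anyDuplicated(x$accession) > 0) abort("accession ids must be unique")
  x$skin_primary <- match_vocab(x$skin_primary, skin_colors(), "skin_primary")
  x$skin_secondary <- match_vocab(x$skin_secondary, skin_colors(secondary = TRUE), "skin_secondary")
  x$flesh_primary <- match_vocab(x$flesh_primary, flesh_colors(), "flesh_primary")
  x$flesh_secondary <- match_vocab(x$flesh_secondary, flesh_colors(secondary = TRUE), "flesh_secondary")
  for (col in c("tpc", "anthocyanin", intersect(anthocyanidin_names(), names(x)))) {
    v <- x[[col]]
    if (!is.numeric(v) || any(v < 0, na.rm = TRUE)) {
      abort(sprintf("%s must be non-negative numeric", col))
    }
  }
  new_tibble(x, class = "phenotype_table")
}

#' Read and write phenotype CSVs
#'
#' Fixed header `accession, skin_primary, skin_secondary, flesh_primary,
#' flesh_secondary, tpc, anthocyanin` plus optional anthocyanidin columns.
#' `read_phenotypes(write_phenotypes(x))` returns `x` unchanged.
#'
#' @param path CSV file path; `x` a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         colClasses = c(accession = "character"))
  phenotype_table(raw)
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(x, path) {
  stopifnot(inherits(x, "phenotype_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
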