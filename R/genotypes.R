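#' Construct a tetraploid genotype call table
#'
#' One row per (accession, locus) call. A call holds 0--4 distinct observed
#' fragment sizes (tetraploid, allele dosage unobserved); an empty size set
#' is a missing call (the locus amplified no product for that accession).
#'
#' @param calls A data frame with columns `accession`, `locus`, and `sizes`
#'   (a list-column of numeric vectors; `numeric(0)` = missing call).
#' @return A `genotype_table` tibble.
#' @seealso [read_genotype_table()], [binarize()]
#' @export
genotype_table <- function(calls) {
  assert_columns(calls, c("accession", "locus", "sizes"), "genotype table")
  calls <- as_tibble(calls)
  if (anyDuplicated(calls[c("accession", "locus")]) > 0) {
    abort("duplicate (accession, locus) rows in genotype table")
  }
  for (i in seq_len(nrow(calls))) {
    s <- unique(calls$sizes[[i]])
    if (length(s) > 4) {
      abort(sprintf(
        "accession %s, locus %s: %d distinct sizes; a tetraploid call has at most 4",
        calls$accession[i], calls$locus[i], length(s)
      ))
    }
    if (any(s <= 0)) {
      abort(sprintf("accession %s, locus %s: sizes must be positive",
                    calls$accession[i], calls$locus[i]))
    }
    calls$sizes[[i]] <- s
  }
  new_tibble(calls, class = "genotype_table")
}

#' Read a genotype CSV
#'
#' Expects a UTF-8 comma-separated file with header `accession,locus,sizes`;
#' `sizes` is a `;`-joined list of fragment sizes in bp, empty for a missing
#' call. Loci must belong to the supplied panel.
#'
#' @param path CSV file path.
#' @param panel A [locus_panel()]; rows naming loci outside it are rejected.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, panel) {
  stopifnot(inherits(panel, "locus_panel"))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw)[1:3], c("accession", "locus", "sizes"))) {
    abort(sprintf("%s: header must be 'accession,locus,sizes'", path))
  }
  unknown <- setdiff(unique(raw$locus), panel$locus)
  if (length(unknown) > 0) {
    abort(sprintf("%s: unknown locus name(s): %s", path, paste(unknown, collapse = ", ")))
  }
  sizes <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    field <- trimws(raw$sizes[i])
    if (field == "") {
      sizes[[i]] <- numeric(0)
      next
    }
    toks <- strsplit(field, ";", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(trimws(toks)))
    if (anyNA(vals)) {
      abort(sprintf("%s: malformed sizes field on data line %d: '%s'",
                    path, i + 1L, raw$sizes[i]))
    }
    sizes[[i]] <- vals
  }
  genotype_table(tibble(accession = raw$accession, locus = raw$locus, sizes = sizes))
}

#' @rdname read_genotype_table
#' @param genotypes A [genotype_table()] to write.
#' @export
write_genotype_table <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_table"))
  out <- data.frame(
    accession = genotypes$accession,
    locus = genotypes$locus,
    sizes = vapply(genotypes$sizes, function(s) paste(s, collapse = ";"), character(1))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_allele_matrix <- function(tbl, column_map, missing) {
  structure(
    new_tibble(tbl, class = "allele_matrix"),
    column_map = column_map,
    missing = missing
  )
}

#' Binary allele presence/absence matrix
#'
#' `binarize()` converts genotype calls into the binary allelic fingerprint:
#' one column per (locus, allele bin), named `"LOCUS:LABEL"`, cell 1 iff an
#' observed size of that accession's call falls in the bin. Several observed
#' sizes falling in one bin still give a single 1 (presence, not dosage).
#' Missing calls give all-zero cells for the locus and are recorded in a
#' missing mask so downstream similarity can distinguish "absent band" from
#' "no amplification".
#'
#' @param genotypes A [genotype_table()].
#' @param panel A [locus_panel()] covering the genotyped loci.
#' @param strict If `TRUE`, an observed size assignable to no bin is an
#'   error; if `FALSE` (default) such sizes are dropped with a warning.
#' @return An `allele_matrix`: a tibble with an `accession` column followed
#'   by 0/1 integer columns grouped contiguously by locus, carrying the
#'   missing mask (see [missing_mask()]) and the column-to-locus map.
#' @examples
#' panel <- reference_panel()
#' gt <- genotype_table(tibble::tibble(
#'   accession = "ACC001", locus = "STM1049", sizes = list(c(190, 203))
#' ))
#' binarize(gt, panel)
#' @export
binarize <- function(genotypes, panel, strict = FALSE) {
  stopifnot(inherits(genotypes, "genotype_table"), inherits(panel, "locus_panel"))
  loci <- intersect(panel$locus, unique(genotypes$locus))
  accessions <- unique(genotypes$accession)
  column_map <- dplyr::filter(bin_labels(panel), .data$locus %in% loci)
  column_map$column <- paste0(column_map$locus, ":", column_map$label)

  m <- matrix(0L, nrow = length(accessions), ncol = nrow(column_map),
              dimnames = list(accessions, column_map$column))
  miss <- vector("list", nrow(genotypes))
  for (i in seq_len(nrow(genotypes))) {
    acc <- genotypes$accession[i]
    loc <- genotypes$locus[i]
    s <- genotypes$sizes[[i]]
    if (length(s) == 0) {
      miss[[i]] <- tibble(accession = acc, locus = loc)
      next
    }
    labels <- assign_bin(s, panel_locus(panel, loc)$bins[[1]])
    if (anyNA(labels)) {
      bad <- s[is.na(labels)]
      msg <- sprintf("size(s) %s at locus %s (accession %s) fall in no allele bin",
                     paste(bad, collapse = ", "), loc, acc)
      if (strict) abort(msg) else warn(paste0(msg, "; dropped"))
      labels <- labels[!is.na(labels)]
      if (length(labels) == 0) {
        miss[[i]] <- tibble(accession = acc, locus = loc)
        next
      }
    }
    m[acc, paste0(loc, ":", unique(labels))] <- 1L
  }
  missing <- dplyr::bind_rows(miss) %||% tibble(accession = character(), locus = character())
  if (nrow(missing) == 0) missing <- tibble(accession = character(), locus = character())
  tbl <- dplyr::bind_cols(tibble(accession = accessions), as_tibble(m))
  new_allele_matrix(tbl, column_map, missing)
}

#' Accessors for allele-matrix metadata
#'
#' `missing_mask()` returns the (accession, locus) pairs whose call was a
#' missing amplification; `column_map()` maps each 0/1 column to its locus
#' and allele-bin label; `matrix_loci()` lists the loci present;
#' `as_matrix()` returns the bare 0/1 integer matrix with accession
#' rownames.
#'
#' @param x An `allele_matrix` (see [binarize()]).
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "allele_matrix"))
  attr(x, "missing")
}

#' @rdname missing_mask
#' @export
column_map <- function(x) {
  stopifnot(inherits(x, "allele_matrix"))
  attr(x, "column_map")
}

#' @rdname missing_mask
#' @export
matrix_loci <- function(x) unique(column_map(x)$locus)

#' @rdname missing_mask
#' @export
as_matrix <- function(x) {
  stopifnot(inherits(x, "allele_matrix"))
  m <- as.matrix(as.data.frame(x[, -1, drop = FALSE]))
  storage.mode(m) <- "integer"
  rownames(m) <- x$accession
  m
}

#' @export
print.allele_matrix <- function(x, ...) {
  cat(sprintf("# Binary allele matrix: %d accessions x %d allele columns (%d loci), %d missing calls\n",
              nrow(x), ncol(x) - 1L, length(matrix_loci(x)), nrow(missing_mask(x))))
  NextMethod()
}

#' Drop loci that amplified nothing
#'
#' Removes every locus whose allele columns are zero for all accessions
#' (including loci missing in every accession) -- markers that produced no
#' product in any reaction and carry no information. The removed locus names
#' are attached as attribute `"removed_loci"` and reported via a message.
#'
#' @param x An `allele_matrix`.
#' @return The pruned `allele_matrix`; `attr(, "removed_loci")` lists what
#'   was dropped.
#' @export
drop_failed_loci <- function(x) {
  stopifnot(inherits(x, "allele_matrix"))
  cmap <- column_map(x)
  m <- as_matrix(x)
  per_locus <- vapply(split(cmap$column, cmap$locus)[unique(cmap$locus)],
                      function(cols) sum(m[, cols, drop = FALSE]), numeric(1))
  failed <- names(per_locus)[per_locus == 0]
  if (length(failed) == 0) {
    attr(x, "removed_loci") <- character(0)
    return(x)
  }
  keep_cols <- cmap$column[!cmap$locus %in% failed]
  if (length(keep_cols) == 0) {
    warn("every locus failed to amplify; returning an empty matrix")
  }
  inform(sprintf("dropping %d locus/loci with no amplification: %s",
                 length(failed), paste(failed, collapse = ", ")))
  out <- new_allele_matrix(
    x[, c("accession", keep_cols), drop = FALSE],
    cmap[cmap$column %in% keep_cols, ],
    dplyr::filter(missing_mask(x), !.data$locus %in% failed)
  )
  attr(out, "removed_loci") <- failed
  out
}

#' Read and write the binary allele matrix as CSV
#'
#' Layout: first column `accession`, remaining columns `"LOCUS:LABEL"` with
#' 0/1 cells. The missing-amplification mask is not representable in this
#' layout; a matrix read back from CSV has an empty mask.
#'
#' @param x An `allele_matrix`; `path` a CSV file path.
#' @return `read_matrix()` returns an `allele_matrix`; `write_matrix()`
#'   invisibly returns `path`.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "allele_matrix"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (names(raw)[1] != "accession") abort(sprintf("%s: first column must be 'accession'", path))
  cols <- names(raw)[-1]
  if (!all(grepl(":", cols, fixed = TRUE))) {
    abort(sprintf("%s: allele columns must be named 'LOCUS:LABEL'", path))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!all(vals %in% c(0L, 1L))) abort(sprintf("%s: cells must be 0/1", path))
  cmap <- tibble(
    locus = sub(":.*$", "", cols),
    label = sub("^[^:]*:", "", cols),
    column = cols
  )
  new_allele_matrix(
    dplyr::bind_cols(tibble(accession = as.character(raw$accession)),
                     as_tibble(raw[, -1, drop = FALSE])),
    cmap,
    tibble(accession = character(), locus = character())
  )
}
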