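# Bundled published summary values for the 290-accession Chilotanum
# native-potato genebank collection, used to reproduce the printed
# arithmetic identities of its characterization (per-cluster above-mean
# counts, class-mean fold ratios, content ranges). The raw per-accession
# data of that collection are not publicly deposited; these summaries are
# the published aggregates.

#' Published reference summaries of the 290-accession potato collection
#'
#' `reference_cluster_counts()` returns the published per-cluster counts of
#' accessions above the population mean for TPC and anthocyanin content
#' (clusters A--G). `reference_content_values()` returns published scalar
#' summaries of the content distributions (population means, medians,
#' ranges and flesh-color class means, µg/g DW).
#'
#' @return A tibble: `cluster`, `trait`, `n_above` for the counts;
#'   `quantity`, `value` for the scalars.
#' @seealso [reference_panel()] for the matching SSR panel with published
#'   PIC values.
#' @export
reference_cluster_counts <- function() {
  path <- system.file("extdata", "reported_cluster_counts.csv",
                      package = "ssrdiv", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname reference_cluster_counts
#' @export
reference_content_values <- function() {
  path <- system.file("extdata", "reported_content_values.csv",
                      package = "ssrdiv", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
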