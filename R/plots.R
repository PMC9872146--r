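# ggplot2 visualizations for result objects

#' @method autoplot ssr_diversity
#' @export
autoplot.ssr_diversity <- function(object, ...) {
  df <- as_tibble(object)
  df$locus <- factor(df$locus, levels = df$locus[order(df$pic)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$pic)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Polymorphism information content (PIC)") +
    ggplot2::theme_minimal()
}

#' @method autoplot above_mean_summary
#' @export
autoplot.above_mean_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$n_above,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "black"),
                               name = "Enriched") +
    ggplot2::labs(
      x = "Genetic cluster",
      y = sprintf("Accessions above mean %s", attr(object, "trait"))
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot ssr_enrichment
#' @export
autoplot.ssr_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  df$neglog <- -log10(df$p_adj)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$value,
                                   fill = .data$neglog)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE], size = 1) +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = expression(-log[10] ~ p[adj])) +
    ggplot2::labs(x = "Genetic cluster", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the Evanno delta-K profile
#'
#' @param delta_k Output of [evanno_delta_k()].
#' @return A ggplot object: delta-K against K (interior K only).
#' @export
plot_delta_k <- function(delta_k) {
  df <- delta_k[!is.na(delta_k$delta_k), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$delta_k)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "K (assumed populations)", y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}
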