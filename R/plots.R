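# ggplot2 views of the pipeline's result tables.

#' Manhattan plot of per-SNP variance shares
#'
#' Chromosome-wise plot of the percentage of a trait's genetic variance
#' explained by each SNP, with the selection threshold drawn as a line.
#'
#' @param effects Tibble from [variance_share()].
#' @param trait Trait to plot.
#' @param threshold Selection threshold (%; drawn as a horizontal line).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(effects, trait, threshold = 0.001) {
  col <- paste0("varpct_", trait)
  if (!col %in% names(effects)) stop_bad_arg("no variance-share column for trait")
  df <- effects |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(x = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data[[col]],
                                   color = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "SNP (genome order)",
                  y = sprintf("%% of genetic variance (%s)", trait)) +
    ggplot2::theme_minimal()
}

#' Enrichment result plot
#'
#' Horizontal bars of -log10 adjusted p-value per pathway, faceted by
#' category, with the significance cutoff marked.
#'
#' @param object [enrich()] output.
#' @param alpha Significance level used for the cutoff line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssgwas_enrichment <- function(object, alpha = 0.05, ...) {
  df <- dplyr::filter(object, !is.na(.data$p_adjusted))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$p_adjusted, 1e-300)),
    y = stats::reorder(.data$pathway_id, -.data$p_adjusted),
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = expression(-log[10]~adjusted~italic(p)),
                  y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}

#' Degree-distribution plot of a PPI network
#'
#' @param net [filter_ppi_edges()] result.
#' @return A ggplot bar chart of node counts per degree.
#' @export
plot_degree_distribution <- function(net) {
  ds <- degree_stats(net)
  ggplot2::ggplot(ds$distribution,
                  ggplot2::aes(x = .data$degree, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "connections per gene", y = "number of genes") +
    ggplot2::theme_minimal()
}
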