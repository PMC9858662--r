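#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of cross-domain pervasiveness
#'
#' Tile plot of the pervasiveness matrix: combinations on the y axis,
#' domains on the x axis, fill = fraction of genomes carrying the
#' combination.
#'
#' @param object A `trna_pervasiveness` table.
#' @param value Cell value to plot (`"pervasiveness"` or `"mean_cn"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trna_pervasiveness
#' @export
autoplot.trna_pervasiveness <- function(object, value = "pervasiveness", ...) {
  df <- tibble::as_tibble(object)
  df$combination <- paste(df$isotype, df$anticodon, sep = "/")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$domain, y = .data$combination,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = if (value == "pervasiveness") c(0, 1) else NULL) +
    ggplot2::labs(x = NULL, y = "isotype/anticodon", fill = value) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Log-log scatter of copy number against genome size
#'
#' @param censuses Census tibble.
#' @param metadata Metadata tibble.
#' @param y Census variable for the y axis (default `"total_trna"`).
#' @return A ggplot object: log10-log10 scatter coloured by domain with
#'   per-domain least-squares lines.
#' @export
plot_scaling <- function(censuses, metadata, y = "total_trna") {
  joined <- join_metadata(censuses, metadata)
  joined <- joined[joined[[y]] > 0 & joined$genome_size_mb > 0, ]
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$genome_size_mb,
                                       y = .data[[y]],
                                       colour = .data$domain)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genome size (Mb)", y = y) +
    ggplot2::theme_minimal()
}

#' Per-type tRF length spectrum
#'
#' @param object A `trf_spectrum` table from [length_spectrum()].
#' @param ... Unused.
#' @return A ggplot bar chart of non-redundant fragment counts by
#'   length, faceted by tRF type.
#' @method autoplot trf_spectrum
#' @export
autoplot.trf_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~trf_type, ncol = 1L) +
    ggplot2::labs(x = "fragment length (nt)", y = "non-redundant tRFs") +
    ggplot2::theme_minimal()
}

#' Boxplot of a census variable by domain
#'
#' @param censuses Census tibble.
#' @param metadata Metadata tibble.
#' @param var Census variable (default `"total_trna"`).
#' @param log10_scale Use a log10 y axis?
#' @return A ggplot object.
#' @export
plot_census_by_domain <- function(censuses, metadata, var = "total_trna",
                                  log10_scale = TRUE) {
  joined <- join_metadata(censuses, metadata)
  p <- ggplot2::ggplot(joined, ggplot2::aes(x = .data$domain,
                                            y = .data[[var]],
                                            fill = .data$domain)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = var) +
    ggplot2::theme_minimal()
  if (log10_scale) p <- p + ggplot2::scale_y_log10()
  p
}
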