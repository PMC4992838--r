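#' Synteny dot plot
#'
#' One panel per molecule pair, a point per homologous gene pair at the two
#' gene midpoints, coloured by strand concordance (the forward/reverse
#' colouring conventional in whole-genome dot plots).
#'
#' @param pairs output of [dotplot_pairs()].
#' @return a ggplot object.
#' @export
plot_dotplot <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$x_pos / 1e6,
                                      y = .data$y_pos / 1e6,
                                      colour = .data$strand_concordance)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_grid(ggplot2::vars(.data$y_mol), ggplot2::vars(.data$x_mol),
                        scales = "free") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#e7548c",
                                            `FALSE` = "#4575b4"),
                                 na.value = "grey50",
                                 name = "same strand") +
    ggplot2::labs(x = "position (Mb)", y = "position (Mb)") +
    ggplot2::theme_bw()
}

#' Ks distribution histogram
#'
#' @param ks_bins output of [ks_histogram()], or a named list of them (one
#'   per species pair) drawn as overlaid frequency polygons.
#' @return a ggplot object.
#' @export
plot_ks_histogram <- function(ks_bins) {
  if (is.data.frame(ks_bins)) ks_bins <- list(`Ks` = ks_bins)
  df <- dplyr::bind_rows(ks_bins, .id = "comparison")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start + diff(df$bin_end[1:2]) / 2,
                                   y = .data$proportion,
                                   colour = .data$comparison)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Ks", y = "proportion of gene pairs", colour = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Pseudomolecule composition plot for an anchoring run
#'
#' Bar per pseudomolecule showing component versus gap bases.
#'
#' @param object an `anchor_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.anchor_run <- function(object, ...) {
  tab <- object$pseudomolecules$table |>
    dplyr::transmute(name = .data$name,
                     scaffold = .data$length_bp - .data$n_gap_bases,
                     gap = .data$n_gap_bases) |>
    tidyr::pivot_longer(c("scaffold", "gap"), names_to = "class",
                        values_to = "bp")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$name, y = .data$bp / 1e6,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(scaffold = "#33a02c",
                                          gap = "grey70")) +
    ggplot2::labs(x = NULL, y = "length (Mb)", fill = NULL) +
    ggplot2::theme_bw()
}
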