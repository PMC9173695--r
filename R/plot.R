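#' Colour-track plot of codon attributions
#'
#' Renders one coloured segment per codon along the sequence axis, stacked
#' as three panels for the three reading frames. Positive attributions
#' (towards lncRNA) are blue, negative (towards mRNA) are red, with colour
#' intensity proportional to magnitude.
#'
#' @param object A `codon_tracks` object (or, for `autoplot.numeric` usage,
#'   pass a nucleotide track through [codon_aggregate()] first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codon_tracks <- function(object, ...) {
  df <- tidy(object)
  lim <- max(abs(df$value), 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = 0, yend = 0,
                                   colour = .data$value)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$frame),
                        labeller = ggplot2::label_both) +
    ggplot2::scale_colour_gradient2(low = "red", mid = "grey95",
                                    high = "blue", limits = c(-lim, lim),
                                    name = "attribution") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (nt)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot attributions for one sequence and optionally write an image
#'
#' @param x A `codon_tracks` object or a numeric per-nucleotide track (which
#'   is codon-aggregated first).
#' @param record Optional one-row records tibble used for the plot title.
#' @param out Optional output path (`.png`, `.svg` or `.pdf`); when given the
#'   plot is written there.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly if `out` is given.
#' @export
plot_attribution <- function(x, record = NULL, out = NULL,
                             width = 8, height = 4) {
  if (is.numeric(x)) x <- codon_aggregate(x)
  stopifnot(inherits(x, "codon_tracks"))
  p <- autoplot(x)
  if (!is.null(record)) {
    p <- p + ggplot2::ggtitle(record$id[[1L]])
  }
  if (is.null(out)) return(p)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = 150)
  invisible(p)
}

#' Bar plot of k-mer impacts
#'
#' @param object A [kmer_impact()] tibble.
#' @param top Show at most this many k-mers per class panel, ranked by
#'   impact.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_kmer_impact <- function(object, top = 16L, ...) {
  df <- object |>
    dplyr::filter(.data$count > 0L) |>
    dplyr::group_by(.data$class) |>
    dplyr::slice_max(.data$mean_abs_shap, n = top) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$kmer, .data$mean_abs_shap),
    y = .data$mean_abs_shap)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free") +
    ggplot2::labs(x = NULL, y = "mean |attribution|") +
    ggplot2::theme_minimal()
}

#' Training-history plot
#'
#' @param object A trained `lnc_cnn`.
#' @param ... Unused.
#' @return A ggplot object with loss and accuracy per epoch.
#' @export
autoplot.lnc_cnn <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("loss", "accuracy"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::theme_minimal()
}
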