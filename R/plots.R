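#' Plot a gating result
#'
#' Bar chart of population sizes (percent of total) for one gated sample.
#'
#' @param object A `cg_gating` from [run_strategy()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_gating <- function(object, ...) {
  df <- object$populations
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$node, .data$pct_total),
    y = .data$pct_total)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of total events",
                  title = "Gated populations")
}

#' Plot a QQ distribution-shift curve
#'
#' Quantile-quantile curve against the identity line; departure from
#' `y = x` shows how the comparison distribution shifted relative to the
#' reference.
#'
#' @param object A `cg_qq` from [qq_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_qq <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$q_x, .data$q_y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8, colour = "firebrick") +
    ggplot2::labs(x = "reference quantiles", y = "comparison quantiles",
                  subtitle = sprintf("median shift %.3f, signed area %.3f",
                                     object$median_shift,
                                     object$signed_area))
}

#' Heat map of Cohen's q differential correlations
#'
#' The display object of the differential-correlation screen: pairwise
#' Cohen's q between injury and sham correlation structures.
#'
#' @param object A `cg_corr_diff`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_corr_diff <- function(object, ...) {
  qm <- object$q_matrix
  df <- tibble::as_tibble(qm, rownames = "marker_1") |>
    tidyr::pivot_longer(-"marker_1", names_to = "marker_2",
                        values_to = "cohens_q")
  ggplot2::ggplot(df, ggplot2::aes(.data$marker_1, .data$marker_2,
                                   fill = .data$cohens_q)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "green3",
                                  high = "red", midpoint = 0.25) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Cohen's q")
}

#' Density or marker-intensity view of a tSNE embedding
#'
#' @param object A `cg_embedding`.
#' @param events Optional aligned event tibble for a marker overlay.
#' @param channel Optional channel name to colour by.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_embedding <- function(object, events = NULL, channel = NULL,
                                  ...) {
  df <- object$coords
  if (!is.null(channel)) {
    df$intensity <- events[[channel]]
    ggplot2::ggplot(df, ggplot2::aes(.data$tsne_1, .data$tsne_2,
                                     colour = .data$intensity)) +
      ggplot2::geom_point(size = 0.4) +
      ggplot2::scale_colour_viridis_c() +
      ggplot2::labs(colour = channel)
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$tsne_1, .data$tsne_2)) +
      ggplot2::geom_hex(bins = 40) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(fill = "events")
  }
}

#' Significance grid of the per-marker screen
#'
#' Mirrors the tabular presentation of the single-marker analysis:
#' parameters by comparison, tiles coloured by direction of the significant
#' shifts.
#'
#' @param screen Tibble from [marker_screen()].
#' @return A ggplot.
#' @export
plot_marker_screen <- function(screen) {
  ggplot2::ggplot(screen, ggplot2::aes(
    x = paste(.data$panel, .data$hemisphere), y = .data$parameter,
    fill = .data$direction)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(up = "firebrick",
                                          down = "steelblue",
                                          none = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "direction vs sham")
}
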