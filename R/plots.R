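CLADE_COLOURS <- c(C = "gold", F = "steelblue3", G = "firebrick",
                   EMPTY = "grey85")

#' Map a simulation state
#'
#' Tile map of clade occupancy, clade C in yellow, F in blue, G in red,
#' empty habitable cells in grey.
#'
#' @param object a `clade_state`.
#' @param landscape optional `clade_landscape` (adds empty habitable cells).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.clade_state <- function(object, landscape = NULL, ...) {
  df <- tidy(object, landscape = landscape)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$clade)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = CLADE_COLOURS) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "clade",
                  title = sprintf("t = %.3g Ma", object$time)) +
    ggplot2::theme_minimal()
}

#' Plot a sampling-site table
#'
#' @param sites site tibble (planar or geographic) with a `clade` column.
#' @return A ggplot object.
#' @export
plot_sites <- function(sites) {
  cc <- site_coords(sites)
  df <- tibble(x = cc$x, y = cc$y, clade = sites$clade)
  lab <- if (cc$geometry == "planar") c("x (km)", "y (km)") else
    c("longitude", "latitude")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$clade)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = CLADE_COLOURS) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = lab[1], y = lab[2], colour = "clade") +
    ggplot2::theme_minimal()
}

#' Posterior histograms of a rejection-ABC fit
#'
#' One panel per parameter with the accepted draws, the posterior median
#' (solid line) and the 95% credible bounds (dashed); the alpha panel also
#' marks the neutral value 0.5 (dotted).
#'
#' @param object a `clade_abc` fit.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.clade_abc <- function(object, ...) {
  long <- tidyr::pivot_longer(object$accepted, c("r", "m", "s", "alpha"),
                              names_to = "parameter")
  marks <- dplyr::bind_rows(
    tibble(parameter = names(object$point),
           value = unname(object$point), kind = "median"),
    tibble(parameter = rep(colnames(object$ci95), each = 2),
           value = c(object$ci95), kind = "ci95"),
    tibble(parameter = "alpha", value = 0.5, kind = "neutral")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey60") +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$value, linetype = .data$kind)
    ) +
    ggplot2::scale_linetype_manual(
      values = c(median = "solid", ci95 = "dashed", neutral = "dotted")
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "accepted draws", linetype = NULL) +
    ggplot2::theme_minimal()
}
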