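#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ROC curves of a benchmark run
#'
#' @param x An `mea_roc` (or a named list of them, one per detector).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_roc <- function(x, ...) {
  if (inherits(x, "mea_roc")) x <- list(detector = x)
  df <- bind_rows(lapply(names(x), function(nm)
    mutate(x[[nm]]$curves, detector = nm)))
  df <- df |>
    group_by(.data$detector, .data$fp_hz) |>
    summarise(tp = mean(.data$tp), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$fp_hz, .data$tp,
                                   colour = .data$detector)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = c(0, x[[1]]$max_fp_hz)) +
    ggplot2::labs(x = "false positive rate (Hz / channel)",
                  y = "true positive fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mea_roc <- function(object, ...) plot_roc(object, ...)

#' Spatial map of detected events
#'
#' @param events An event tibble.
#' @param bin_um Hex-bin width (default 21).
#' @return A ggplot object.
#' @export
plot_events <- function(events, bin_um = 21) {
  ggplot2::ggplot(events, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_bin2d(binwidth = c(bin_um, bin_um)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "events") +
    ggplot2::theme_minimal()
}

#' Plot a direction-bias map
#'
#' Arrows show the local direction towards coincident activity; colour the
#' bias magnitude in units of three null standard deviations (1 = clearly
#' non-random).
#'
#' @param x An `mea_biasmap` from [direction_bias_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_bias_map <- function(x, ...) {
  df <- filter(x, .data$n > 0)
  sc <- max(df$bias, na.rm = TRUE)
  arrow_um <- 15 / max(sc, 1e-9)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_tile(ggplot2::aes(fill = pmin(.data$bias, 1.5))) +
    ggplot2::geom_segment(ggplot2::aes(
      xend = .data$x_um + .data$bias_x * arrow_um,
      yend = .data$y_um + .data$bias_y * arrow_um),
      linewidth = 0.2, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "bias (3 SD units)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mea_biasmap <- function(object, ...) plot_bias_map(object, ...)

#' Plot per-unit correlation classification
#'
#' @param x An `mea_classification` from [classify_events()].
#' @param ... Unused.
#' @return A ggplot showing per-unit uncorrelated fractions.
#' @export
autoplot.mea_classification <- function(x, ...) {
  df <- filter(x$units, .data$method != "flagged")
  ggplot2::ggplot(df, ggplot2::aes(.data$fraction_uncorrelated,
                                   fill = .data$method)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0) +
    ggplot2::labs(x = "estimated fraction of uncorrelated events",
                  y = "units") +
    ggplot2::theme_minimal()
}
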