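#' Plot methods
#'
#' `autoplot()` methods give quick-look ggplots for every result type: the
#' raw trace with optional detected troughs, the segment-averaged spectrum on
#' log-power axes, the stimulus raster of a protocol, and the sector-by-layer
#' density map.
#'
#' @param object a `bq_recording`, `bq_spectrum`, `bq_protocol` or
#'   `bq_density`.
#' @param troughs optional `bq_events` overlaid on a recording trace.
#' @param ... unused.
#' @return a ggplot object.
#' @name burstquant-autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname burstquant-autoplot
#' @export
autoplot.bq_recording <- function(object, troughs = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$uv)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "LFP (µV)") +
    ggplot2::theme_minimal()
  if (!is.null(troughs) && nrow(troughs) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = troughs$time_s,
                                 colour = "red", alpha = 0.4,
                                 linewidth = 0.2)
  }
  p
}

#' @rdname burstquant-autoplot
#' @export
autoplot.bq_spectrum <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$freq_hz > 0),
                  ggplot2::aes(x = .data$freq_hz, y = .data$power_uv2)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(power ~ (mu * V^2))) +
    ggplot2::theme_minimal()
}

#' @rdname burstquant-autoplot
#' @export
autoplot.bq_protocol <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$time_s, y = 0, yend = 1),
                          linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%.1f stimuli/min", protocol_rate(object))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname burstquant-autoplot
#' @export
autoplot.bq_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sector,
                                       y = factor(.data$layer,
                                                  levels = rev(unique(.data$layer))),
                                       fill = .data$density_per_mm2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(cells / mm^2)) +
    ggplot2::labs(x = "sector (medial → lateral)", y = "layer band") +
    ggplot2::theme_minimal()
}
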