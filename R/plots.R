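#' Plot an estimated single-trial ERP
#'
#' Smoothed poststimulus estimate, optionally overlaid on the raw sweep it
#' was computed from.
#'
#' @param object An `estimated_erp`.
#' @param raw Optional numeric vector (the raw poststimulus samples).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.estimated_erp <- function(object, raw = NULL, ...) {
  df <- tidy.estimated_erp(object)
  df$series <- "estimate"
  if (!is.null(raw)) {
    df <- dplyr::bind_rows(
      tibble::tibble(time_ms = df$time_ms, amplitude = raw, series = "raw"), df
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(raw = "grey60", estimate = "firebrick")) +
    ggplot2::labs(x = "time after stimulus (ms)", y = expression(amplitude ~ (mu * V)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of SC vs MC accuracy by testing day
#'
#' The per-day, per-system accuracy distributions of both groups, drawn as
#' box plots (median, quartile box, whiskers) like the published
#' comparison figure.
#'
#' @param tables Long tibble from [load_accuracy_tables()].
#' @return A ggplot, faceted by group.
#' @export
plot_accuracy_distributions <- function(tables) {
  ggplot2::ggplot(tables, ggplot2::aes(.data$day, .data$accuracy,
                                       fill = .data$system)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8),
                          width = 0.6, outlier.shape = 1) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "testing day", y = "accuracy (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ERP template
#'
#' @param object An [make_erp_template()] object.
#' @param ... Unused.
#' @return A ggplot of the template waveform.
#' @exportS3Method ggplot2::autoplot
autoplot.erp_template <- function(object, ...) {
  df <- tibble::tibble(
    time_ms = (seq_along(object$waveform) - 1) / object$fs_hz * 1000,
    amplitude = object$waveform
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time after stimulus (ms)", y = expression(amplitude ~ (mu * V))) +
    ggplot2::theme_minimal()
}
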