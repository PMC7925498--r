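# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot MRM traces
#'
#' Intensity against retention time, one facet per transition channel.
#'
#' @param object an `sq_traces` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sq_traces <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$time_min, y = .data$intensity)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$transition_id),
                        scales = "free_y") +
    ggplot2::labs(x = "Retention time (min)", y = "Intensity (counts)")
}

#' Plot a calibration curve
#'
#' Calibration levels with the fitted line and the LOQ marked.
#'
#' @param object an `sq_calibration` object.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sq_calibration <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = .data$conc, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::geom_vline(xintercept = object$loq_ug_ml, linetype = 2) +
    ggplot2::labs(
      x = "Concentration (µg/mL)",
      y = "Response (analyte area / ISD area)",
      subtitle = sprintf("R² = %.4f; LOQ = %.3g µg/mL (dashed)",
                         object$r_squared, object$loq_ug_ml)
    )
}

#' Plot composition shares
#'
#' Bar chart of each analyte's share of the total sulfolipid content.
#'
#' @param object an `sq_quant` tibble or the output of
#'   [composition_shares()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sq_quant <- function(object, ...) {
  x <- tibble::as_tibble(object)
  x <- x[!is.na(x$share_percent), ]
  ggplot2::ggplot(
    x,
    ggplot2::aes(x = stats::reorder(.data$analyte, -.data$share_percent),
                 y = .data$share_percent)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Analyte", y = "Share of total content (%)")
}

#' @rdname autoplot.sq_quant
#' @export
plot_composition <- function(object, ...) {
  if (!"share_percent" %in% names(object)) {
    object <- composition_shares(object)
    class(object) <- c("sq_quant", class(object))
    object$flag <- ""
  }
  autoplot.sq_quant(object, ...)
}
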