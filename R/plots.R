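# ggplot2 autoplot methods

#' Plot a CV trace as a voltammogram or time series
#'
#' @param object A [cv_trace()].
#' @param mode `"iv"` (current vs voltage, the classic voltammogram) or
#'   `"time"` (current and voltage vs time).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_trace <- function(object, mode = c("iv", "time"), ...) {
  mode <- match.arg(mode)
  meta <- trace_meta(object)
  ttl <- sprintf(
    "%s (%s, %g cells/500 uL)",
    meta$sample_id %||% "CV trace", meta$cell_type %||% "?",
    meta$concentration %||% NA
  )
  if (mode == "iv") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$voltage_V, y = .data$current_A * 1e9)) +
      ggplot2::geom_path(colour = "#2c7fb8") +
      ggplot2::labs(x = "Potential (V)", y = "Current (nA)", title = ttl) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$current_A * 1e9)) +
      ggplot2::geom_line(colour = "#2c7fb8") +
      ggplot2::labs(x = "Time (s)", y = "Current (nA)", title = ttl) +
      ggplot2::theme_minimal()
  }
}

#' Plot an extracted capacitance trace
#'
#' Valid samples only; capacitance in uF against time.
#'
#' @param object A `cap_trace` or `deembedded_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cap_trace <- function(object, ...) {
  d <- filter(as_tibble(object), .data$valid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = farads_to_uF(.data$capacitance_F))) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::labs(x = "Time (s)", y = "Capacitance (uF)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cap_trace
#' @param value For de-embedded traces: plot the dimensionless `"ratio"` or
#'   the `"rescaled"` farad-scale curve.
#' @exportS3Method ggplot2::autoplot
autoplot.deembedded_trace <- function(object, value = c("rescaled", "ratio"), ...) {
  value <- match.arg(value)
  d <- filter(as_tibble(object), .data$valid)
  if (value == "rescaled") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = farads_to_uF(.data$rescaled_F))) +
      ggplot2::geom_line(colour = "#1b9e77") +
      ggplot2::labs(x = "Time (s)", y = "De-embedded capacitance (uF)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$ratio)) +
      ggplot2::geom_line(colour = "#1b9e77") +
      ggplot2::labs(x = "Time (s)", y = "Sample / media capacitance ratio") +
      ggplot2::theme_minimal()
  }
}

#' Plot a concentration-response
#'
#' @param object A [build_concentration_response()] result.
#' @param ... Unused.
#' @return A ggplot (log-10 concentration axis).
#' @exportS3Method ggplot2::autoplot
autoplot.concentration_response <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$concentration, y = farads_to_uF(.data$capacitance_F))
  ) +
    ggplot2::geom_point(colour = "#7570b3") +
    ggplot2::geom_line(colour = "#7570b3") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Concentration (cells / 500 uL)", y = "Capacitance (uF)",
      title = sprintf(
        "%s at %.2f s", object$cell_type[1],
        attr(object, "reference_time")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-type mean capacitance with SEM bars
#'
#' @param object A [summarize_phenotype()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phenotype_summary <- function(object, ...) {
  d <- tidy.phenotype_summary(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$cell_type, .data$rank),
    y = .data$mean_uF
  )) +
    ggplot2::geom_col(fill = "#66a61e", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_uF - .data$sem_uF,
        ymax = .data$mean_uF + .data$sem_uF
      ),
      width = 0.15
    ) +
    ggplot2::labs(x = NULL, y = "Mean capacitance (uF)") +
    ggplot2::theme_minimal()
}

#' Plot per-type mean areas with SEM bars
#'
#' @param object A [compare_type_areas()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.area_comparison <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$cell_type, .data$rank),
    y = .data$mean_um2
  )) +
    ggplot2::geom_col(fill = "#e6ab02", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_um2 - .data$sem_um2,
        ymax = .data$mean_um2 + .data$sem_um2
      ),
      width = 0.15
    ) +
    ggplot2::labs(x = NULL, y = expression("Mean area (" * mu * m^2 * ")")) +
    ggplot2::theme_minimal()
}
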