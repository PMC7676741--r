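#' Plot methods
#'
#' ggplot2 visualizations of the main result types: displacement density
#' curves, regional box summaries, the voiding time course, and flow metric
#' time series.
#'
#' @param object the result object.
#' @param ... unused.
#' @return A ggplot object.
#' @name vesica-plots
NULL

#' @rdname vesica-plots
#' @export
autoplot.displacement_field <- function(object, ...) {
  dens <- displacement_density(object)
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$d0_mm, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "wall displacement d0 (mm)", y = "probability density",
                  title = "Bladder wall displacement distribution") +
    ggplot2::theme_minimal()
}

#' @rdname vesica-plots
#' @export
autoplot.regional_stats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$max),
      stat = "identity", fill = "steelblue", alpha = 0.6
    ) +
    ggplot2::labs(x = NULL, y = "displacement d0 (mm)",
                  title = "Regional wall displacement",
                  subtitle = sprintf("left-right asymmetry %.1f%%",
                                     attr(object, "asymmetry_pct"))) +
    ggplot2::theme_minimal()
}

#' @rdname vesica-plots
#' @export
autoplot.alpha_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$alpha)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (s)", y = expression(alpha(t)),
                  title = "Voiding time-dependence function") +
    ggplot2::theme_minimal()
}

#' @rdname vesica-plots
#' @export
autoplot.voiding_kinematics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_s", "volume_mm3", "flow_ml_s")],
    cols = c("volume_mm3", "flow_ml_s"),
    names_to = "quantity", values_to = "value"
  )
  labs <- c(volume_mm3 = "bladder volume (mm^3)", flow_ml_s = "flow rate (mL/s)")
  long$quantity <- labs[long$quantity]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Voiding kinematics") +
    ggplot2::theme_minimal()
}

#' @rdname vesica-plots
#' @export
autoplot.flow_solution <- function(object, ...) {
  met <- flow_metrics(object)
  long <- tidyr::pivot_longer(met, cols = -"time_s",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Voiding flow metrics") +
    ggplot2::theme_minimal()
}
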