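#' Plot a fitted flight curve
#'
#' Draws the logistic flight curve on the degree-day axis; for fitted models
#' the logit-scale training points are shown back-transformed.
#'
#' @param object A `flight_fit`.
#' @param dd_range Degree-day range; defaults to the 0.5%-99.5% region of
#'   the curve (or the data range when wider).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.flight_fit <- function(object, dd_range = NULL, ...) {
  if (is.null(dd_range)) {
    dd_range <- dd_at_fraction(object, c(0.005, 0.995))
    if (!is.null(object$data)) {
      dd_range <- range(c(dd_range, object$data$dd))
    }
  }
  grid <- tibble(dd = seq(dd_range[1], dd_range[2], length.out = 200))
  grid$cum_prop <- predict(object, grid$dd)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$dd, y = .data$cum_prop)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Degree-days from biofix (°C-days)",
      y = "Cumulative proportion of flight",
      title = object$label
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    pts <- tibble(dd = object$data$dd, cum_prop = plogis(object$data$lp))
    p <- p + ggplot2::geom_point(data = pts, shape = 1)
  }
  p
}

#' Plot confidence and prediction bands
#'
#' The inner ribbon is the confidence band for the mean response, the outer
#' ribbon the prediction band for a new observation; optionally overlays
#' observed points.
#'
#' @param object A `prediction_band`.
#' @param observed Optional observed curve (`dd`, `cum_prop`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.prediction_band <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$dd)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pi_low, ymax = .data$pi_high),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(
      x = "Degree-days from biofix (°C-days)",
      y = "Cumulative proportion of flight",
      title = attr(object, "label"),
      subtitle = paste0(100 * attr(object, "level"),
                        "% confidence (inner) and prediction (outer) bands")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(
      data = as_tibble(observed),
      ggplot2::aes(x = .data$dd, y = .data$cum_prop), shape = 1
    )
  }
  p
}

#' Plot mean seasonal capture series
#'
#' Mean per-trap capture (+/- SEM) against check date, faceted by stratum:
#' the seasonal flight-pattern view on which generation cutoffs are read
#' off.
#'
#' @param msc Output of [mean_seasonal_capture()].
#' @param by Facet columns present in `msc`.
#' @return A ggplot.
#' @export
plot_seasonal_capture <- function(msc, by = c("orchard_type", "lure")) {
  by <- intersect(by, names(msc))
  p <- ggplot2::ggplot(msc, ggplot2::aes(x = .data$check_date,
                                         y = .data$mean_capture)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_capture - .data$sem,
      ymax = .data$mean_capture + .data$sem
    ), linewidth = 0.3, size = 0.25, na.rm = TRUE) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Check date", y = "Mean capture per trap (± SEM)") +
    ggplot2::theme_minimal()
  if (length(by) > 0) {
    p <- p + ggplot2::facet_wrap(stats::reformulate(by))
  }
  p
}
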