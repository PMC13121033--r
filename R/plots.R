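# Plotting and broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flux fit
#'
#' @param x A [flux_fit()] object.
#' @param ... Unused.
#' @return One row per regression term with estimate and standard error.
#' @method tidy flux_fit
#' @export
tidy.flux_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "cvh"),
                 estimate = cf[, 1], std.error = cf[, 2],
                 statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname tidy.flux_fit
#' @method glance flux_fit
#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(metabolite = x$metabolite, slope = x$slope,
                 std.error = x$stderr, r.squared = summary(x$fit)$r.squared,
                 points_used = x$points_used,
                 points_excluded = nrow(x$excluded))
}

#' Plot a flux fit
#'
#' Medium moles against accumulated cell-volume-hours with the fitted
#' regression line; excluded points are marked by exclusion reason.
#'
#' @param object A [flux_fit()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flux_fit
#' @export
autoplot.flux_fit <- function(object, ...) {
  d <- object$data
  d$reason <- "used"
  if (nrow(object$excluded) > 0) {
    d$reason[object$excluded$index] <- object$excluded$reason
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cvh, y = .data$moles)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$reason, shape = .data$reason),
                        size = 2) +
    ggplot2::labs(x = "accumulated cell-volume-hours (ul h)",
                  y = paste0(object$metabolite, " (mol)"),
                  colour = NULL, shape = NULL,
                  title = sprintf("flux %.3g mol/(ul h)", object$slope)) +
    ggplot2::theme_minimal()
}

#' Tidy a calibration fit
#'
#' @param x A [fit_calibration()] object.
#' @param ... Unused.
#' @return One row per coefficient of the selected model.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  cf <- x$fits[[x$model]]$coefficients
  tibble::tibble(term = names(cf), estimate = unname(cf))
}

#' @rdname tidy.calibration_fit
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = unname(x$rss[x$model]),
                 n_standards = nrow(x$standards))
}

#' Plot a calibration fit
#'
#' @param object A [fit_calibration()] object.
#' @param ... Unused.
#' @return A ggplot of the standards and the selected curve.
#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, ...) {
  s <- object$standards
  grid <- tibble::tibble(ratio = seq(min(s$ratio), max(s$ratio),
                                     length.out = 200))
  grid$concentration <- quantify(object, grid$ratio)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$ratio, y = .data$concentration)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = paste("calibration:", object$model, "model")) +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run
#'
#' Per-stage survivor counts of a [run_pipeline()] result.
#'
#' @param object A `trace_run` object.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @method autoplot trace_run
#' @export
autoplot.trace_run <- function(object, ...) {
  cnt <- object$report$stage_counts
  d <- tibble::tibble(stage = factor(names(cnt), levels = names(cnt)),
                      n = as.numeric(cnt))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "rows surviving") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Mass/RT map of detected peak pairs
#'
#' Parent mass against retention time for a pair tibble, coloured by
#' status.
#'
#' @param pairs A pair tibble (any stage).
#' @return A ggplot.
#' @export
plot_pair_map <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$parent_rt,
                                      y = .data$parent_mass,
                                      colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "retention time (min)", y = "neutral mass (Da)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
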