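#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: disparity
#' tuning curves (mean +/- SE), signal-strength and variability surfaces as
#' heat maps over (correlation, density), and psychometric curves with the
#' chance level marked. All plotting is optional; the numeric pipeline never
#' requires a graphics device.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name stereomatch-plots
NULL

#' @rdname stereomatch-plots
#' @export
autoplot.tuning_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(disparity, value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = value - se, ymax = value + se),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "window disparity (px)",
                  y = sprintf("%s output", attr(object, "operator")))
}

#' @rdname stereomatch-plots
#' @export
autoplot.signal_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(correlation, density, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred") +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "binocular correlation", y = "dot density",
                  fill = "signal\nstrength")
}

#' @rdname stereomatch-plots
#' @export
autoplot.sd_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(correlation, density, fill = sd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "binocular correlation", y = "dot density",
                  fill = "SD of\ndifferential signal")
}

#' @rdname stereomatch-plots
#' @export
autoplot.psychometric_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(100 * correlation, pct_correct)) +
    ggplot2::geom_hline(yintercept = 50, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pct_correct - se,
                                          ymax = pct_correct + se)) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "binocular correlation (%)", y = "correct (%)",
                  title = sprintf("%s model, density %d%%",
                                  attr(object, "model"),
                                  round(100 * attr(object, "density"))))
}

#' @rdname stereomatch-plots
#' @export
autoplot.psychometric_family <- function(object, ...) {
  df <- strip_result_class(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(100 * correlation, pct_correct)) +
    ggplot2::geom_hline(yintercept = 50, linetype = 3) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "binocular correlation (%)", y = "correct (%)")
  if ("noise_sigma" %in% names(df))
    p + ggplot2::facet_grid(density ~ noise_sigma,
                            labeller = ggplot2::label_both)
  else p + ggplot2::facet_wrap(~density, labeller = ggplot2::label_both)
}

#' Render a receptive field or contrast image as a heat map
#'
#' @param x A numeric matrix (e.g. from [make_receptive_field()]) or a
#'   contrast image.
#' @return A ggplot object.
#' @export
plot_field <- function(x) {
  df <- tidyr::expand_grid(y = seq_len(nrow(x)), x_ = seq_len(ncol(x)))
  df$value <- x[cbind(df$y, df$x_)]
  ggplot2::ggplot(df, ggplot2::aes(x_, y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50",
                                  high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
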