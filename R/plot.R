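#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectrum
#' @param object a [power_spectrum].
#' @param log_freq plot the frequency axis on a log scale (default TRUE).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.power_spectrum <- function(object, log_freq = TRUE, ...) {
  df <- tibble::as_tibble(object)
  if (log_freq) df <- df[df$freq > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (units²/Hz)")
  if (log_freq) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot a forward model as a channel x delay image
#' @param object a [backward_to_forward()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.forward_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delay_s * 1000,
                                   y = .data$channel, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "Delay (ms)", y = "Channel", fill = "Weight")
}

#' Plot an adjusted spectrum with its noise floor
#' @param object an [adjust_psd()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.adjusted_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$adjusted)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Adjusted PSD")
}

#' Plot band-sweep z-scored accuracies
#'
#' @param sweep a [run_band_sweep()] result.
#' @return a ggplot of median z per band against the band centre frequency.
#' @export
plot_band_sweep <- function(sweep) {
  df <- sweep$results
  agg <- stats::aggregate(z ~ window_s + band_lo_hz + band_hi_hz, df, stats::median)
  agg$f_centre <- sqrt(agg$band_lo_hz * agg$band_hi_hz)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$f_centre, y = .data$z)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Band centre frequency (Hz)",
                  y = "Median z-scored reconstruction accuracy")
}

#' @importFrom ggplot2 .data
NULL
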