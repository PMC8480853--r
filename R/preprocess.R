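#' Remove a centered moving average
#'
#' Subtracts from every sample the mean of a centered window of
#' `round(window_s * rate)` samples; windows are truncated at the signal
#' edges. This acts as a high-pass filter with cutoff near `1/window_s`:
#' a sinusoid whose period equals the window length is untouched in the
#' interior (the mean over a full period is zero), while slower components
#' and the DC offset are removed.
#'
#' @param x numeric vector, or matrix with channels in rows.
#' @param window_s window length in seconds.
#' @param rate sampling rate in Hz.
#' @return same shape as `x`.
#' @export
remove_moving_average <- function(x, window_s, rate) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, remove_moving_average, window_s = window_s, rate = rate)))
  }
  n <- round(window_s * rate)
  L <- length(x)
  if (n < 1) stop("moving-average window must span at least one sample", call. = FALSE)
  if (n > L) stop("moving-average window longer than the signal", call. = FALSE)
  a <- (n - 1L) %/% 2L          # samples before the centre
  b <- n - 1L - a               # samples after
  cs <- c(0, cumsum(x))
  t <- seq_len(L)
  lo <- pmax(1L, t - a)
  hi <- pmin(L, t + b)
  sums <- cs[hi + 1L] - cs[lo]
  x - sums / (hi - lo + 1L)
}
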