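#' Power spectrum container
#'
#' A one-sided power spectral density on an ascending frequency grid.
#'
#' @param freq numeric vector of frequencies in Hz, strictly increasing.
#' @param power numeric vector of spectral density values (units^2/Hz),
#'   non-negative, same length as `freq`.
#' @return an object of class `power_spectrum` (also a tibble with columns
#'   `freq` and `power`).
#' @export
power_spectrum <- function(freq, power) {
  stopifnot(length(freq) == length(power))
  if (any(!is.finite(freq)) || any(diff(freq) <= 0)) {
    stop("`freq` must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(power)) || any(power < -1e-15)) {
    stop("`power` must be finite and non-negative", call. = FALSE)
  }
  out <- tibble::tibble(freq = freq, power = pmax(power, 0))
  class(out) <- c("power_spectrum", class(out))
  out
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hamming taper. Segments of
#' `window_s` seconds overlap by `overlap_frac`; each is tapered, Fourier
#' transformed, and the one-sided density is averaged across segments.
#' Scaling is such that for white noise the mean density times the Nyquist
#' bandwidth approximates the signal variance.
#'
#' @param x numeric time series.
#' @param rate sampling rate in Hz.
#' @param window_s segment length in seconds (must not exceed the signal
#'   duration).
#' @param overlap_frac fractional overlap between successive segments,
#'   in `[0, 1)`; default 0.5 (half overlap).
#' @param demean subtract the segment mean before tapering (default FALSE;
#'   the modelling pipeline removes means upstream).
#' @return a [power_spectrum].
#' @export
welch_psd <- function(x, rate, window_s, overlap_frac = 0.5, demean = FALSE) {
  if (!is.numeric(window_s) || window_s <= 0) {
    stop("`window_s` must be positive", call. = FALSE)
  }
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("`overlap_frac` must be in [0, 1)", call. = FALSE)
  }
  n <- length(x)
  nseg <- round(window_s * rate)
  if (nseg < 2 || nseg > n) {
    stop("signal shorter than one Welch window", call. = FALSE)
  }
  step <- max(1L, round(nseg * (1 - overlap_frac)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- hamming_window(nseg)
  u <- sum(w^2)            # taper power normalization
  nfft <- nseg
  nf <- nfft %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[1:nf]
    p <- (Mod(X)^2) / (rate * u)
    # one-sided: double all bins except DC (and Nyquist when nfft is even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (nfft %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  freq <- (0:(nf - 1L)) * rate / nfft
  power_spectrum(freq, acc / length(starts))
}

# periodic Hamming taper (matches the convention used for Welch averaging)
hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / n)
}

#' Phase-randomized surrogate of a real signal
#'
#' Returns a real-valued surrogate with the same Fourier amplitude spectrum
#' as `x` but uniformly random phases. Phases are drawn conjugate-symmetric;
#' the DC and (for even lengths) Nyquist components are left untouched so the
#' surrogate is exactly real and its periodogram magnitudes match the
#' original to machine precision.
#'
#' @param x numeric vector.
#' @return numeric vector, same length as `x`.
#' @export
phase_randomize <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  X <- stats::fft(x)
  half <- if (n %% 2L == 0L) (n %/% 2L - 1L) else ((n - 1L) %/% 2L)
  idx <- 2L:(1L + half)
  phi <- stats::runif(half, 0, 2 * pi)
  X[idx] <- Mod(X[idx]) * exp(1i * phi)
  X[n + 2L - idx] <- Conj(X[idx])
  Re(stats::fft(X, inverse = TRUE)) / n
}
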