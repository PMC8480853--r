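#' Cubic B-spline collocation basis over a delay window
#'
#' Builds evenly spaced knots at `knot_rate` spanning the delay range
#' `[0, window_s]`, augments the end knots to order 4 (cubic), and evaluates
#' every basis spline at every EEG sample delay in the window. The number of
#' basis splines is `window_s * knot_rate + 3`; e.g. a 500 ms window with
#' knots sampled at 8, 16, 32, 64 Hz yields 7, 11, 19, 35 splines. Rows of
#' the collocation matrix sum to one (partition of unity).
#'
#' @param window_s delay window length in seconds.
#' @param knot_rate sampling rate of the spline knots in Hz; must divide the
#'   window into a whole number of intervals and not exceed `eeg_rate`.
#' @param eeg_rate EEG sampling rate in Hz.
#' @return an object of class `spline_basis`: list with `S` (collocation
#'   matrix, delays x splines), `delays_s` (delay grid in seconds),
#'   `window_s`, `knot_rate`, `eeg_rate`, `knots`.
#' @export
build_spline_basis <- function(window_s, knot_rate, eeg_rate) {
  if (window_s <= 0) stop("`window_s` must be positive", call. = FALSE)
  if (knot_rate <= 0 || knot_rate > eeg_rate) {
    stop("need 0 < knot_rate <= eeg_rate", call. = FALSE)
  }
  if (!is_whole(window_s * knot_rate)) {
    nearest <- round(window_s * knot_rate) / window_s
    stop(sprintf(
      "window_s * knot_rate must be a whole number of knot intervals; nearest valid knot_rate is %g Hz",
      nearest), call. = FALSE)
  }
  n_int <- round(window_s * knot_rate)
  interior <- seq(0, window_s, length.out = n_int + 1L)
  knots <- c(rep(0, 3), interior, rep(window_s, 3))
  delays <- seq(0, round(window_s * eeg_rate)) / eeg_rate
  S <- splines::splineDesign(knots, delays, ord = 4)
  structure(list(S = S, delays_s = delays, window_s = window_s,
                 knot_rate = knot_rate, eeg_rate = eeg_rate, knots = knots),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis> %g s window, knots at %g Hz: %d delays x %d splines\n",
              x$window_s, x$knot_rate, nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' Number of basis splines
#' @param basis a [spline_basis].
#' @return integer count of basis splines (columns of the collocation matrix).
#' @export
n_splines <- function(basis) ncol(basis$S)

#' Time-lagged design matrix
#'
#' Stacks delayed copies of each input signal into a design matrix with
#' time along rows. Feature layout is component-major, delay-minor: the
#' block of columns for component `c` holds that signal delayed by each
#' entry of `delays_ms` in order. Samples shifted in from outside the
#' recording are zero.
#'
#' @param signals matrix (components x time) or a numeric vector (one
#'   component).
#' @param delays_ms numeric vector of delays in milliseconds (positive
#'   delays look back in time; negative delays look ahead).
#' @param rate sampling rate in Hz.
#' @return matrix (time x `n_components * n_delays`) with attributes
#'   `delays_ms` and `n_components`.
#' @export
build_lag_matrix <- function(signals, delays_ms, rate) {
  if (length(delays_ms) == 0) stop("`delays_ms` must be non-empty", call. = FALSE)
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  k <- nrow(signals); T_ <- ncol(signals)
  d_samp <- round(delays_ms / 1000 * rate)
  if (any(abs(d_samp) >= T_)) {
    stop("delays exceed the signal duration", call. = FALSE)
  }
  nd <- length(d_samp)
  X <- matrix(0, T_, k * nd)
  for (c in seq_len(k)) {
    for (j in seq_len(nd)) {
      d <- d_samp[j]
      col <- numeric(T_)
      if (d >= 0) {
        if (d < T_) col[(d + 1L):T_] <- signals[c, 1:(T_ - d)]
      } else {
        col[1:(T_ + d)] <- signals[c, (1L - d):T_]
      }
      X[, (c - 1L) * nd + j] <- col
    }
  }
  attr(X, "delays_ms") <- delays_ms
  attr(X, "n_components") <- k
  X
}

# delay grid of a model window, in milliseconds (0 .. window, inclusive)
model_delays_ms <- function(window_s, eeg_rate, center = FALSE) {
  d <- seq(0, round(window_s * eeg_rate)) / eeg_rate * 1000
  if (center) d <- d - stats::median(d)
  d
}

#' Project a lag matrix onto the spline basis
#'
#' Per component block, computes `Xs = Xd S (S'S)^{-1}` so that `Xs S'` is
#' the least-squares spline approximation of the rows of `Xd`. When the
#' basis is collocated at full resolution (`knot_rate = eeg_rate`) the
#' normal matrix is rank-deficient; a minimum-norm pseudo-inverse is used
#' with a warning.
#'
#' @param Xd lag matrix from [build_lag_matrix]; the delay count per
#'   component must equal the rows of the collocation matrix.
#' @param basis a [spline_basis].
#' @return matrix (time x `n_components * n_splines`) with attribute
#'   `n_components`.
#' @export
spline_project <- function(Xd, basis) {
  stopifnot(inherits(basis, "spline_basis"))
  k <- attr(Xd, "n_components")
  if (is.null(k)) stop("`Xd` must come from build_lag_matrix()", call. = FALSE)
  nd <- ncol(Xd) / k
  S <- basis$S
  if (nd != nrow(S)) {
    stop("delay count per component does not match the collocation matrix",
         call. = FALSE)
  }
  P <- t(spd_solve(crossprod(S), t(S)))   # nd x ns projection
  ns <- ncol(S)
  Xs <- matrix(0, nrow(Xd), k * ns)
  for (c in seq_len(k)) {
    Xs[, (c - 1L) * ns + seq_len(ns)] <-
      Xd[, (c - 1L) * nd + seq_len(nd), drop = FALSE] %*% P
  }
  attr(Xs, "n_components") <- k
  Xs
}

#' Convert spline-space weights to delay-space weights
#'
#' Applies `w_d = S w_s` per component, mapping model weights from the
#' spline basis back onto the delay grid.
#'
#' @param w_s matrix (components x splines).
#' @param basis a [spline_basis].
#' @return matrix (components x delays).
#' @export
weights_to_delays <- function(w_s, basis) {
  stopifnot(inherits(basis, "spline_basis"))
  if (is.vector(w_s)) w_s <- matrix(w_s, nrow = 1)
  if (ncol(w_s) != ncol(basis$S)) {
    stop("spline dimension does not match the basis", call. = FALSE)
  }
  w_s %*% t(basis$S)
}

#' Band-limiting behaviour of the moving-average + spline chain
#'
#' Characterizes the model pipeline as a filter by driving it with white
#' noise: the moving average over the model window is removed, a lag matrix
#' with delays centered on zero is built and projected onto the spline
#' basis, a least-squares fit of the processed noise is computed, and the
#' gain is the ratio of the Welch amplitude spectra of the reconstruction
#' and of the original noise. The passband is approximately
#' `[1/window_s, knot_rate/2]`, a three-octave range for the 19-spline
#' configuration.
#'
#' @param spec a [model_spec]; only `window_s`, `knot_rate`, `eeg_rate` are
#'   used.
#' @param noise_len_s duration of the white-noise probe in seconds (much
#'   longer than the window).
#' @param seed integer RNG seed.
#' @param psd_window_s Welch window for the gain estimate (default 4 s).
#' @return tibble of class `filter_response` with columns `freq` (Hz) and
#'   `gain_db`.
#' @export
characterize_filter <- function(spec, noise_len_s, seed, psd_window_s = 4) {
  stopifnot(inherits(spec, "model_spec"))
  if (noise_len_s < 10 * spec$window_s) {
    stop("`noise_len_s` must be much longer than the model window", call. = FALSE)
  }
  set.seed(seed)
  fs <- spec$eeg_rate
  x <- stats::rnorm(round(noise_len_s * fs))
  y <- remove_moving_average(x, spec$window_s, fs)
  basis <- build_spline_basis(spec$window_s, spec$knot_rate, fs)
  delays <- model_delays_ms(spec$window_s, fs, center = TRUE)
  Xd <- build_lag_matrix(y, delays, fs)
  Xs <- spline_project(Xd, basis)
  b <- lstsq(Xs, y)
  recon <- drop(Xs %*% b)
  edge <- round(spec$window_s * fs) + 1L
  keep <- (edge + 1L):(length(x) - edge)
  p_in <- welch_psd(x[keep], fs, psd_window_s)
  p_out <- welch_psd(recon[keep], fs, psd_window_s)
  out <- tibble::tibble(freq = p_in$freq,
                        gain_db = 10 * log10(pmax(p_out$power, 1e-300) /
                                               pmax(p_in$power, 1e-300)))
  class(out) <- c("filter_response", class(out))
  out
}
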