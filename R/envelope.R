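#' Audio waveform container
#'
#' @param samples numeric vector of pressure amplitudes (arbitrary linear
#'   units); must be finite.
#' @param rate sampling rate in Hz, positive.
#' @return object of class `audio_waveform`.
#' @export
audio_waveform <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a positive scalar", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("audio contains non-finite samples", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "audio_waveform")
}

#' Envelope container
#'
#' Holds a stimulus level trace in dB re the peak (0 dB at the loudest
#' point), clipped below at `floor_db`.
#'
#' @param samples numeric vector of dB values, all `>= floor_db`.
#' @param rate sampling rate in Hz.
#' @param floor_db clipping floor in dB (default -100).
#' @return object of class `envelope`.
#' @export
envelope <- function(samples, rate, floor_db = -100) {
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive", call. = FALSE)
  if (any(!is.finite(samples))) stop("envelope samples must be finite", call. = FALSE)
  if (any(samples < floor_db - 1e-9)) {
    stop("envelope samples below `floor_db`", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), rate = rate,
                 floor_db = floor_db), class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %.1f s at %g Hz, floor %g dB, range [%.1f, %.1f] dB\n",
              length(x$samples) / x$rate, x$rate, x$floor_db,
              min(x$samples), max(x$samples)))
  invisible(x)
}

# duration in seconds
env_duration <- function(env) length(env$samples) / env$rate

# analytic-signal magnitude via the frequency domain
hilbert_magnitude <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1, n %/% 2 + 1)] <- 1
    h[2:(n %/% 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) %/% 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Equivalent rectangular bandwidth of the auditory filter at centre f (Hz)
erb_hz <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Gammatone filterbank impulse responses
#'
#' Order-4 gammatone filters, `g(t) = t^3 exp(-2 pi b ERB(fc) t) cos(2 pi fc t)`
#' with `b = 1.019`, centre frequencies in geometric progression between
#' `f_lo` and `f_hi` (endpoints included). Each impulse response is
#' normalized to unit peak magnitude response at its centre frequency.
#'
#' @param n_bands number of filters.
#' @param f_lo,f_hi centre-frequency endpoints in Hz.
#' @param rate sampling rate in Hz.
#' @param dur_s impulse-response duration in seconds (default 0.128).
#' @return list with `ir` (matrix, n_bands x samples) and `cf` (centre
#'   frequencies).
#' @export
gammatone_filterbank <- function(n_bands, f_lo, f_hi, rate, dur_s = 0.128) {
  stopifnot(n_bands >= 1, f_lo > 0, f_lo < f_hi, f_hi < rate / 2)
  cf <- if (n_bands == 1L) sqrt(f_lo * f_hi) else
    exp(seq(log(f_lo), log(f_hi), length.out = n_bands))
  t <- seq(0, dur_s, by = 1 / rate)
  ir <- matrix(0, n_bands, length(t))
  for (i in seq_len(n_bands)) {
    b <- 1.019 * erb_hz(cf[i])
    g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf[i] * t)
    # unit gain at the centre frequency
    gain <- Mod(sum(g * exp(-2i * pi * cf[i] * t)))
    ir[i, ] <- g / gain
  }
  list(ir = ir, cf = cf)
}

# causal FIR filtering by FFT convolution, output aligned with the input
fir_filter <- function(x, h) {
  n <- length(x); m <- length(h)
  nfft <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(h, numeric(nfft - m))), inverse = TRUE)) / nfft
  y[1:n]
}

#' Extract the dB stimulus envelope from audio
#'
#' Filters the waveform with a bank of gammatone filters logarithmically
#' spaced between `f_lo` and `f_hi`, takes the magnitude of the analytic
#' signal in each band, averages the magnitudes across bands, normalizes
#' the peak to 1, clips values below `10^(floor_db/20)`, converts to dB,
#' and resamples the dB trace to `out_rate` (dB first, then resampling).
#'
#' @param audio an [audio_waveform].
#' @param n_bands number of filterbank channels (default 32).
#' @param f_lo,f_hi filterbank centre-frequency range in Hz (defaults
#'   100 Hz and 8 kHz).
#' @param floor_db clipping floor in dB (default -100).
#' @param out_rate output sampling rate in Hz (default 512).
#' @return an [envelope].
#' @export
extract_envelope <- function(audio, n_bands = 32, f_lo = 100, f_hi = 8000,
                             floor_db = -100, out_rate = 512) {
  stopifnot(inherits(audio, "audio_waveform"))
  if (f_hi >= audio$rate / 2 || f_lo >= f_hi) {
    stop("need f_lo < f_hi < rate/2", call. = FALSE)
  }
  fb <- gammatone_filterbank(n_bands, f_lo, f_hi, audio$rate)
  if (length(audio$samples) < ncol(fb$ir)) {
    stop("audio shorter than one filter impulse response", call. = FALSE)
  }
  acc <- numeric(length(audio$samples))
  for (i in seq_len(n_bands)) {
    acc <- acc + hilbert_magnitude(fir_filter(audio$samples, fb$ir[i, ]))
  }
  env_lin <- acc / n_bands
  pk <- max(env_lin)
  if (pk > 0) env_lin <- env_lin / pk   # digital silence stays at zero
  env_lin <- pmax(env_lin, 10^(floor_db / 20))
  env_db <- 20 * log10(env_lin)
  if (!isTRUE(all.equal(out_rate, audio$rate))) {
    pq <- rat_approx(out_rate / audio$rate)
    env_db <- as.numeric(signal::resample(env_db, pq[["p"]], pq[["q"]]))
    env_db <- pmax(env_db, floor_db)   # guard against resampling ripple
  }
  envelope(env_db, out_rate, floor_db)
}

#' Welch spectrum of an envelope
#'
#' @param env an [envelope].
#' @param window_s Hamming window length in seconds (default 16).
#' @param overlap_frac fractional overlap (default 0.5).
#' @return a [power_spectrum].
#' @export
envelope_psd <- function(env, window_s = 16, overlap_frac = 0.5) {
  stopifnot(inherits(env, "envelope"))
  if (window_s <= 0) stop("`window_s` must be positive", call. = FALSE)
  if (env_duration(env) < window_s) {
    stop("envelope shorter than the analysis window", call. = FALSE)
  }
  welch_psd(env$samples, env$rate, window_s, overlap_frac)
}

#' Normalize envelopes for spectral comparison against EEG
#'
#' Preprocessing preset for envelope/EEG power ratios: each dB envelope is
#' zero-centered, a long moving average (default 16 s, the largest model
#' window) is subtracted, and all traces are divided by the square root of
#' the mean variance across stimuli so the set has unit average variance.
#'
#' @param envs list of [envelope] objects sharing one sampling rate.
#' @param ma_window_s moving-average window in seconds (default 16).
#' @return list of numeric vectors (normalized traces).
#' @export
normalize_envelopes <- function(envs, ma_window_s = 16) {
  stopifnot(length(envs) >= 1)
  rate <- envs[[1]]$rate
  traces <- lapply(envs, function(e) {
    stopifnot(inherits(e, "envelope"), isTRUE(all.equal(e$rate, rate)))
    x <- e$samples - mean(e$samples)
    remove_moving_average(x, ma_window_s, rate)
  })
  vbar <- mean(vapply(traces, stats::var, numeric(1)))
  lapply(traces, function(x) x / sqrt(vbar))
}

#' Channel-averaged, z-scored EEG noise trace
#'
#' Averages EEG across channels, removes a long moving average and z-scores
#' the result; its Welch spectrum is the denominator of the envelope/EEG
#' power ratio.
#'
#' @param eeg matrix, channels x samples.
#' @param rate sampling rate in Hz.
#' @param ma_window_s moving-average window in seconds (default 16).
#' @return numeric vector.
#' @export
eeg_noise_trace <- function(eeg, rate, ma_window_s = 16) {
  x <- colMeans(as.matrix(eeg))
  x <- remove_moving_average(x, ma_window_s, rate)
  zscore_vec(x, "EEG noise trace")
}

#' Envelope-to-EEG power ratio
#'
#' Bin-wise ratio of the average envelope spectrum to the (trial- and
#' subject-averaged) EEG spectrum. All spectra must share one frequency grid.
#'
#' @param env_psds list of [power_spectrum] objects (one per envelope).
#' @param eeg_psd a [power_spectrum] for the averaged EEG.
#' @return a [power_spectrum] whose `power` column holds the unitless ratio.
#' @export
envelope_eeg_power_ratio <- function(env_psds, eeg_psd) {
  stopifnot(length(env_psds) >= 1, inherits(eeg_psd, "power_spectrum"))
  f0 <- env_psds[[1]]$freq
  for (p in env_psds) {
    if (!isTRUE(all.equal(p$freq, f0)) ) {
      stop("power spectra are not on a common frequency grid", call. = FALSE)
    }
  }
  if (!isTRUE(all.equal(eeg_psd$freq, f0))) {
    stop("EEG spectrum is not on the envelope frequency grid", call. = FALSE)
  }
  if (any(eeg_psd$power <= 0)) {
    stop("EEG spectrum has zero power in at least one bin", call. = FALSE)
  }
  env_avg <- Reduce(`+`, lapply(env_psds, function(p) p$power)) / length(env_psds)
  power_spectrum(f0, env_avg / eeg_psd$power)
}

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader supporting 16- and 24-bit PCM and 32-bit float
#' data. Multichannel files are averaged to mono.
#'
#' @param path path to a `.wav` file.
#' @return an [audio_waveform].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        rate     = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt or data chunk", call. = FALSE)
  x <- switch(
    as.character(fmt$bits),
    "16" = readBin(dat, "integer", length(dat) %/% 2, 2, signed = TRUE,
                   endian = "little") / 2^15,
    "24" = {
      n <- length(dat) %/% 3
      b <- matrix(as.integer(dat[seq_len(3 * n)]), nrow = 3)
      v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    },
    "32" = {
      if (fmt$format == 3) {
        readBin(dat, "double", length(dat) %/% 4, 4, endian = "little")
      } else {
        readBin(dat, "integer", length(dat) %/% 4, 4, endian = "little") / 2^31
      }
    },
    stop("unsupported bit depth: ", fmt$bits, call. = FALSE))
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_waveform(x, fmt$rate)
}
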