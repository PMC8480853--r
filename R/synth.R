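#' Ground-truth spatiotemporal response kernel
#'
#' Difference-of-gammas time course (positive peak near 100 ms, trough near
#' 200 ms, the canonical shape of an auditory evoked response) with a smooth
#' spatial gradient across channels.
#'
#' @param n_channels number of EEG channels.
#' @param rate sampling rate in Hz.
#' @param dur_s kernel duration in seconds (default 0.35).
#' @return matrix (channels x delays).
#' @export
synth_kernel <- function(n_channels, rate, dur_s = 0.35) {
  t <- seq(0, dur_s, by = 1 / rate)
  peak <- stats::dgamma(t, shape = 6, rate = 50)    # mode at 0.1 s
  trough <- stats::dgamma(t, shape = 6, rate = 25)  # mode at 0.2 s
  tc <- peak / max(peak) - 0.7 * trough / max(trough)
  gradient <- seq(1, 0.3, length.out = n_channels)  # frontal-to-parietal falloff
  outer(gradient, tc)
}

#' 1/f^alpha noise
#'
#' White Gaussian noise spectrally shaped to a power-law spectrum and
#' rescaled to unit standard deviation. `alpha = 0` gives white noise,
#' `alpha = 1` pink noise.
#'
#' @param n number of samples.
#' @param alpha spectral exponent (>= 0).
#' @return numeric vector of length `n`, sd 1.
#' @export
pink_noise <- function(n, alpha = 1) {
  stopifnot(alpha >= 0, n >= 2)
  W <- stats::fft(stats::rnorm(n))
  nf <- n %/% 2L
  fidx <- c(1, seq_len(n - 1))          # avoid 1/0 at DC
  shape <- 1 / pmin(fidx, n - fidx + 1)^(alpha / 2)
  shape[1] <- 0                          # remove DC
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthetic-data configuration
#'
#' Study conditions for the generator: a known channels x delays response
#' kernel convolved with a stimulus envelope plus 1/f noise at a controlled
#' signal-to-noise variance ratio.
#'
#' @param n_channels channels (default 16).
#' @param eeg_rate EEG sampling rate in Hz (default 64).
#' @param duration_s trial length in seconds (default 60).
#' @param kernel channels x delays matrix; default [synth_kernel()].
#' @param noise_exponent 1/f^alpha slope (default 1).
#' @param snr per-channel signal-to-noise variance ratio (> 0; may be `Inf`).
#' @param envelope_kind one of `"sparse"` (speech-like shot noise with a
#'   ~0.3 Hz amplitude modulation), `"periodic"` (music-like pulse train at
#'   a tempo, with harmonics), `"flat"` (Gaussian, near-white in the model
#'   band).
#' @param tempo beat rate in Hz for the periodic kind (default 2).
#' @param floor_db envelope clipping floor (default -100).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 16, eeg_rate = 64, duration_s = 60,
                         kernel = NULL, noise_exponent = 1, snr = 1,
                         envelope_kind = c("sparse", "periodic", "flat"),
                         tempo = 2, floor_db = -100) {
  envelope_kind <- match.arg(envelope_kind)
  if (is.null(kernel)) kernel <- synth_kernel(n_channels, eeg_rate)
  stopifnot(snr > 0, noise_exponent >= 0, tempo > 0,
            nrow(kernel) == n_channels)
  if (duration_s * eeg_rate <= 2 * ncol(kernel)) {
    stop("trial too short for the kernel", call. = FALSE)
  }
  structure(list(n_channels = n_channels, eeg_rate = eeg_rate,
                 duration_s = duration_s, kernel = kernel,
                 noise_exponent = noise_exponent, snr = snr,
                 envelope_kind = envelope_kind, tempo = tempo,
                 floor_db = floor_db), class = "synth_config")
}

#' Generate a synthetic stimulus envelope
#'
#' Produces a linear envelope with the statistical structure of the
#' configured stimulus kind, smooths it, normalizes the peak to 1, clips at
#' the floor and converts to dB (matching the envelope-extraction contract).
#' The RNG state at call time determines the realization; seed upstream for
#' reproducibility.
#'
#' @param config a [synth_config].
#' @return an [envelope]; for the periodic kind the beat times (seconds) are
#'   attached as attribute `beats`.
#' @export
synth_envelope <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$eeg_rate
  n <- round(config$duration_s * fs)
  t <- (0:(n - 1)) / fs
  pulse <- function(width_s) {
    m <- max(3L, round(width_s * fs))
    0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
  }
  beats <- NULL
  lin <- switch(config$envelope_kind,
    sparse = {
      n_ev <- stats::rpois(1, 4 * config$duration_s)   # ~4 bursts/s
      ev <- numeric(n)
      pos <- sample.int(n, min(n_ev, n))
      ev[pos] <- stats::rexp(length(pos))
      x <- fir_filter(ev, pulse(0.05))
      am <- 0.55 + 0.45 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
      x * am + 0.01
    },
    periodic = {
      beats <- seq(0.5, config$duration_s - 0.5, by = 1 / config$tempo)
      ev <- numeric(n)
      ev[pmin(n, round(beats * fs) + 1L)] <- 1
      fir_filter(ev, pulse(0.03)) + 0.02
    },
    flat = {
      z <- stats::rnorm(n)
      z <- stats::filter(z, rep(1 / 2, 2), sides = 1)
      z[is.na(z)] <- 0
      exp(0.25 * z)
    })
  lin <- lin / max(lin)
  lin <- pmax(lin, 10^(config$floor_db / 20))
  env <- envelope(20 * log10(lin), fs, config$floor_db)
  if (!is.null(beats)) attr(env, "beats") <- beats
  env
}

#' Generate synthetic EEG from an envelope and a known kernel
#'
#' Each channel is the (z-scored, dB) envelope convolved with that channel's
#' kernel row, plus independent 1/f^alpha noise scaled so the per-channel
#' signal-to-noise variance ratio equals `config$snr`.
#'
#' @param env an [envelope].
#' @param config a [synth_config].
#' @return matrix (channels x samples).
#' @export
synth_eeg <- function(env, config) {
  stopifnot(inherits(env, "envelope"), inherits(config, "synth_config"))
  if (config$snr <= 0) stop("snr must be positive", call. = FALSE)
  s <- zscore_vec(env$samples, "envelope")
  n <- length(s)
  if (ncol(config$kernel) > n) stop("kernel longer than the envelope", call. = FALSE)
  eeg <- matrix(0, config$n_channels, n)
  for (ch in seq_len(config$n_channels)) {
    sig <- fir_filter(s, config$kernel[ch, ])
    if (is.finite(config$snr)) {
      noise <- pink_noise(n, config$noise_exponent) *
        stats::sd(sig) / sqrt(config$snr)
      eeg[ch, ] <- sig + noise
    } else {
      eeg[ch, ] <- sig
    }
  }
  eeg
}

#' Generate a synthetic trial set with ground truth attached
#'
#' Trials are assigned to classes in round-robin order; each class can carry
#' its own envelope kind, tempo, kernel and SNR (defaults inherited from
#' `config`). The generating kernel is attached to every trial for
#' parameter-recovery tests, and beat times are attached for periodic
#' classes.
#'
#' @param config a [synth_config] holding the shared conditions.
#' @param n_trials number of trials (>= 1).
#' @param classes named list of per-class overrides (each a list with any of
#'   `envelope_kind`, `tempo`, `kernel`, `snr`); default one class named
#'   after `config$envelope_kind`.
#' @param seed integer RNG seed.
#' @return list of [eeg_trial] objects; each has fields `kernel` (ground
#'   truth) and, when periodic, `beats`.
#' @export
synth_trialset <- function(config, n_trials, classes = NULL, seed = 1) {
  stopifnot(inherits(config, "synth_config"), n_trials >= 1)
  set.seed(seed)
  if (is.null(classes)) {
    classes <- stats::setNames(list(list()), config$envelope_kind)
  }
  cls_names <- names(classes)
  lapply(seq_len(n_trials), function(i) {
    cls <- cls_names[(i - 1L) %% length(classes) + 1L]
    ov <- classes[[cls]]
    cfg <- config
    for (f in names(ov)) cfg[[f]] <- ov[[f]]
    env <- synth_envelope(cfg)
    eeg <- synth_eeg(env, cfg)
    tr <- eeg_trial(eeg, cfg$eeg_rate, env, class = cls,
                    beats = attr(env, "beats"))
    tr$kernel <- cfg$kernel
    tr
  })
}
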