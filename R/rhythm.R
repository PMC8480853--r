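#' Welch spectrum of an envelope reconstruction
#'
#' @param recon numeric reconstruction time series.
#' @param rate sampling rate in Hz.
#' @param window_s Hamming window length in seconds (default 10).
#' @param overlap_frac fractional overlap (default 0.5).
#' @return a [power_spectrum].
#' @export
reconstruction_psd <- function(recon, rate, window_s = 10, overlap_frac = 0.5) {
  welch_psd(recon, rate, window_s, overlap_frac)
}

#' Phase-randomized null spectra of averaged reconstructions
#'
#' Estimates the incoherent noise floor of the across-subject average: per
#' iteration every subject's reconstruction is phase-randomized
#' independently, the surrogates are averaged across subjects, and the Welch
#' spectrum of the average is computed. Power that survives averaging in the
#' true data but not in the surrogates reflects temporally coherent
#' structure across subjects.
#'
#' @param per_subject_recons list of equal-length numeric reconstructions,
#'   one per subject.
#' @param rate sampling rate in Hz.
#' @param n_iter number of null spectra (default 100).
#' @param seed integer RNG seed.
#' @param window_s Welch window in seconds (default 10).
#' @return list of `n_iter` [power_spectrum] objects.
#' @export
null_spectra <- function(per_subject_recons, rate, n_iter = 100, seed,
                         window_s = 10) {
  stopifnot(length(per_subject_recons) >= 1, n_iter >= 1)
  lens <- vapply(per_subject_recons, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("reconstructions have unequal lengths", call. = FALSE)
  }
  set.seed(seed)
  lapply(seq_len(n_iter), function(i) {
    surr <- lapply(per_subject_recons, phase_randomize)
    avg <- Reduce(`+`, surr) / length(surr)
    welch_psd(avg, rate, window_s)
  })
}

#' Noise-floor-adjusted power spectral density
#'
#' Subtracts the mean of the null spectra from the true spectrum bin-wise.
#' Positive adjusted values mark frequencies with coherent power above the
#' phase-randomized noise floor; the adjusted spectrum may be negative.
#'
#' @param true_psd a [power_spectrum] of the across-subject average.
#' @param null_psds list of [power_spectrum] objects on the same grid.
#' @return object of class `adjusted_spectrum` (tibble with columns `freq`,
#'   `true_psd`, `null_mean_psd`, `adjusted`).
#' @export
adjust_psd <- function(true_psd, null_psds) {
  stopifnot(inherits(true_psd, "power_spectrum"), length(null_psds) >= 1)
  for (p in null_psds) {
    if (!isTRUE(all.equal(p$freq, true_psd$freq))) {
      stop("null spectra are not on the true spectrum's grid", call. = FALSE)
    }
  }
  null_mean <- Reduce(`+`, lapply(null_psds, function(p) p$power)) /
    length(null_psds)
  tp <- true_psd$power
  out <- tibble::tibble(freq = true_psd$freq, true_psd = tp,
                        null_mean_psd = null_mean,
                        adjusted = tp - null_mean)
  class(out) <- c("adjusted_spectrum", class(out))
  out
}

#' Tempo from beat times
#'
#' The musical beat rate, computed as the inverse of the median inter-beat
#' interval (robust to occasional missed or extra beats).
#'
#' @param beat_times numeric vector of beat times in seconds, strictly
#'   increasing, at least 3 beats.
#' @return tempo in Hz.
#' @export
tempo_from_beats <- function(beat_times) {
  if (length(beat_times) < 3) stop("need at least 3 beats", call. = FALSE)
  d <- diff(beat_times)
  if (any(d <= 0)) stop("beat times must be strictly increasing", call. = FALSE)
  1 / stats::median(d)
}

#' Peaks of adjusted spectra at multiples of the tempo
#'
#' For each tempo multiple `m` the search window is
#' `[0.92 * m * tempo, 1.08 * m * tempo]` (endpoints inclusive); the maximum
#' adjusted power over all supplied spectra within the window is reported.
#' Ties are broken towards the lowest frequency.
#'
#' @param adjusted_spectra list of [adjust_psd()] results on one common grid.
#' @param tempo tempo in Hz (positive).
#' @param multiples integer multiples to search (default `1:4`).
#' @return object of class `tempo_peak_set`: tibble with columns `multiple`,
#'   `f_lo`, `f_hi`, `peak_freq`, `peak_power`, `spectrum`; attribute
#'   `tempo`.
#' @export
find_tempo_peaks <- function(adjusted_spectra, tempo, multiples = 1:4) {
  stopifnot(tempo > 0, length(adjusted_spectra) >= 1)
  f0 <- adjusted_spectra[[1]]$freq
  for (a in adjusted_spectra) {
    if (!isTRUE(all.equal(a$freq, f0))) {
      stop("adjusted spectra are not on a common grid", call. = FALSE)
    }
  }
  if (max(f0) < 1.08 * max(multiples) * tempo) {
    stop("frequency grid does not cover the highest tempo multiple", call. = FALSE)
  }
  rows <- lapply(multiples, function(m) {
    lo <- 0.92 * m * tempo
    hi <- 1.08 * m * tempo
    in_win <- which(f0 >= lo - 1e-12 & f0 <= hi + 1e-12)
    if (length(in_win) == 0) {
      stop(sprintf(
        "no frequency bins inside [%.4g, %.4g] Hz; need resolution <= %.4g Hz",
        lo, hi, hi - lo), call. = FALSE)
    }
    vals <- vapply(adjusted_spectra, function(a) a$adjusted[in_win],
                   numeric(length(in_win)))
    vals <- matrix(vals, nrow = length(in_win))
    bin_max <- apply(vals, 1, max)
    jbest <- which(bin_max == max(bin_max))[1]    # tie: lowest frequency
    sbest <- which(vals[jbest, ] == bin_max[jbest])[1]
    tibble::tibble(multiple = m, f_lo = lo, f_hi = hi,
                   peak_freq = f0[in_win][jbest], peak_power = bin_max[jbest],
                   spectrum = as.integer(sbest))
  })
  out <- do.call(rbind, rows)
  attr(out, "tempo") <- tempo
  class(out) <- c("tempo_peak_set", class(out))
  out
}
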