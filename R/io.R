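#' EEG trial container
#'
#' One trial of multichannel EEG with its stimulus envelope and metadata.
#'
#' @param eeg matrix, channels x samples; finite.
#' @param rate sampling rate in Hz.
#' @param envelope an [envelope] or numeric dB trace, same length as the
#'   EEG.
#' @param channels optional character vector of channel labels (one per
#'   row).
#' @param class stimulus class label (e.g. "speech", "rock").
#' @param beats optional numeric beat times in seconds.
#' @param ref_channels optional character vector naming reference channels
#'   (e.g. mastoids) present in `channels`; [read_trialset()] applies the
#'   re-referencing.
#' @return object of class `eeg_trial`.
#' @export
eeg_trial <- function(eeg, rate, envelope, channels = NULL,
                      class = NA_character_, beats = NULL,
                      ref_channels = NULL) {
  eeg <- as.matrix(eeg)
  if (any(!is.finite(eeg))) stop("EEG contains non-finite values", call. = FALSE)
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive", call. = FALSE)
  env_len <- if (inherits(envelope, "envelope")) length(envelope$samples)
             else length(envelope)
  if (env_len != ncol(eeg)) {
    stop("envelope length does not match the EEG", call. = FALSE)
  }
  if (!is.null(channels) && length(channels) != nrow(eeg)) {
    stop(sprintf("channel label count (%d) does not match EEG rows (%d)",
                 length(channels), nrow(eeg)), call. = FALSE)
  }
  structure(list(eeg = eeg, rate = rate, envelope = envelope,
                 channels = channels, class = class, beats = beats,
                 ref_channels = ref_channels),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> %d channels x %.1f s at %g Hz, class '%s'\n",
              nrow(x$eeg), ncol(x$eeg) / x$rate, x$rate, x$class))
  invisible(x)
}

#' Write a trial set to disk
#'
#' Serializes a list of [eeg_trial] objects to a single container file
#' (R native serialization).
#'
#' @param trials list of [eeg_trial] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(trials, path) {
  stopifnot(all(vapply(trials, inherits, logical(1), "eeg_trial")))
  saveRDS(trials, path)
  invisible(path)
}

#' Read and validate a trial set
#'
#' Loads a container written by [write_trialset()], validates every trial
#' (rate and labels present, finite data), and applies mastoid-style
#' re-referencing when a trial flags reference channels: the average of the
#' reference channels is subtracted from every channel and the reference
#' rows are dropped.
#'
#' @param path container path.
#' @return list of [eeg_trial] objects.
#' @export
read_trialset <- function(path) {
  trials <- readRDS(path)
  if (!is.list(trials)) stop("container does not hold a trial list", call. = FALSE)
  lapply(trials, function(tr) {
    if (!inherits(tr, "eeg_trial")) stop("entry is not an eeg_trial", call. = FALSE)
    if (is.null(tr$rate)) stop("trial is missing field `rate`", call. = FALSE)
    if (any(!is.finite(tr$eeg))) stop("trial EEG contains NaN", call. = FALSE)
    if (!is.null(tr$channels) && length(tr$channels) != nrow(tr$eeg)) {
      stop("trial channel labels do not match the EEG rows", call. = FALSE)
    }
    if (!is.null(tr$ref_channels)) {
      if (is.null(tr$channels)) {
        stop("reference channels flagged but channel labels missing", call. = FALSE)
      }
      ref_idx <- match(tr$ref_channels, tr$channels)
      if (anyNA(ref_idx)) stop("reference channel not found in labels", call. = FALSE)
      ref <- colMeans(tr$eeg[ref_idx, , drop = FALSE])
      tr$eeg <- sweep(tr$eeg[-ref_idx, , drop = FALSE], 2, ref, "-")
      tr$channels <- tr$channels[-ref_idx]
      tr$ref_channels <- NULL
    }
    tr
  })
}

#' Band sweep: reconstruction accuracy across frequency ranges
#'
#' Runs leave-one-trial-out reconstruction and a circular-shift null for a
#' series of model windows (each paired with a knot rate preserving the
#' spline count, hence a constant three-octave bandwidth), and z-scores the
#' accuracies per window.
#'
#' @param trials list of [eeg_trial] objects.
#' @param windows_s numeric vector of model windows in seconds.
#' @param n_components retained components.
#' @param eeg_rate EEG sampling rate in Hz.
#' @param knot_per_window knot intervals per window (default 16, i.e. 19
#'   splines: `knot_rate = 16 / window_s`).
#' @param n_null circular-shift iterations per window (default 50).
#' @param seed integer RNG seed.
#' @param trim_s edge trim in seconds.
#' @return list with `results` (tibble: one row per window x trial with
#'   `window_s`, `band_lo_hz`, `band_hi_hz`, `trial`, `r`, `null_mean`,
#'   `null_sd`, `z`), `forward_models` (one per window), `seed`.
#' @export
run_band_sweep <- function(trials, windows_s, n_components, eeg_rate,
                           knot_per_window = 16, n_null = 50, seed = 1,
                           trim_s = c(15.5, 16)) {
  stopifnot(length(windows_s) >= 1)
  rows <- list(); fwd <- list()
  for (wi in seq_along(windows_s)) {
    w <- windows_s[wi]
    spec <- model_spec(w, knot_per_window / w, n_components, eeg_rate, trim_s)
    loo <- leave_one_out(trials, spec)
    null <- circular_shift_null(trials, spec, n_iter = n_null,
                                seed = seed + wi)
    b <- band_edges(spec)
    zs <- do.call(rbind, lapply(seq_len(nrow(loo)), function(i)
      zscore_accuracy(loo$r[i], null, trial_id = loo$trial[i])))
    zs$window_s <- w
    zs$band_lo_hz <- b[1]
    zs$band_hi_hz <- b[2]
    rows[[wi]] <- zs
    model <- fit_backward_model(trials, spec)
    fwd[[wi]] <- backward_to_forward(model, trials)
  }
  res <- do.call(rbind, rows)
  res <- res[, c("window_s", "band_lo_hz", "band_hi_hz", "trial",
                 "r_true", "null_mean", "null_sd", "z")]
  names(res)[names(res) == "r_true"] <- "r"
  list(results = res, forward_models = fwd, seed = seed)
}
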