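#' Fit a stimulus-general model on pooled trials
#'
#' Identical contract to [fit_backward_model()], applied to trials pooled
#' across all stimulus types. Pairing the pooled model's per-trial accuracy
#' with the stimulus-specific model's accuracy on the same trial quantifies
#' whether a common mechanism explains the tracking.
#'
#' @param all_trials list of [eeg_trial] objects from every stimulus class.
#' @param spec a [model_spec].
#' @return a [fit_backward_model()] result.
#' @export
fit_general_model <- function(all_trials, spec) {
  fit_backward_model(all_trials, spec)
}

#' Fit a general forward model to a specific one by circular shift + scaling
#'
#' Both models are first centered to zero mean per channel. For every
#' circular shift of the general model along the delay axis, the best
#' non-negative per-channel scaling is the clipped closed-form slope
#' `max(0, <g_k, s> / <g_k, g_k>)` (regression without intercept), and the
#' fit quality is `R^2 = 1 - sum SSE / sum SST` pooled over channels. The
#' shift maximizing R^2 is returned; ties go to the smallest absolute shift.
#'
#' @param general,specific [backward_to_forward()] results (or any objects
#'   with a `weights` channels x delays matrix) with matching dimensions.
#' @return object of class `shift_scale_fit`: list with `shift` (signed
#'   samples in `(-n/2, n/2]`), `scale` (per-channel, >= 0), `r_squared`,
#'   and `by_shift` (tibble of R^2 per candidate shift).
#' @export
shift_scale_fit <- function(general, specific) {
  G <- as.matrix(if (is.list(general)) general$weights else general)
  Sp <- as.matrix(if (is.list(specific)) specific$weights else specific)
  if (!all(dim(G) == dim(Sp))) {
    stop("general and specific models differ in dimensions", call. = FALSE)
  }
  G <- G - rowMeans(G)
  Sp <- Sp - rowMeans(Sp)
  sst <- sum(Sp^2)
  if (sst < 1e-20) stop("specific model has zero variance", call. = FALSE)
  n <- ncol(G)
  signed <- function(k) ifelse(k > n / 2, k - n, k)
  r2 <- numeric(n)
  scales <- matrix(0, nrow(G), n)
  for (k in 0:(n - 1L)) {
    idx <- ((seq_len(n) - 1L - k) %% n) + 1L   # row g shifted right by k
    Gk <- G[, idx, drop = FALSE]
    num <- rowSums(Gk * Sp)
    den <- rowSums(Gk * Gk)
    sc <- pmax(0, ifelse(den > 1e-20, num / den, 0))
    resid <- Sp - Gk * sc
    r2[k + 1L] <- 1 - sum(resid^2) / sst
    scales[, k + 1L] <- sc
  }
  ks <- 0:(n - 1L)
  ord <- order(-r2, abs(signed(ks)), -sign(signed(ks)))
  kbest <- ks[ord[1]]
  structure(list(shift = signed(kbest), scale = scales[, kbest + 1L],
                 r_squared = r2[kbest + 1L],
                 by_shift = tibble::tibble(shift = signed(ks), r_squared = r2)),
            class = "shift_scale_fit")
}

#' @export
print.shift_scale_fit <- function(x, ...) {
  cat(sprintf("<shift_scale_fit> shift = %d samples, R^2 = %.4f, median scale = %.3f\n",
              x$shift, x$r_squared, stats::median(x$scale)))
  invisible(x)
}

#' Tidy a shift/scale fit
#' @param x a [shift_scale_fit].
#' @param ... unused.
#' @return tibble with one row per channel: `channel`, `scale`, plus the
#'   shared `shift` and `r_squared`.
#' @export
tidy.shift_scale_fit <- function(x, ...) {
  tibble::tibble(channel = seq_along(x$scale), scale = x$scale,
                 shift = x$shift, r_squared = x$r_squared)
}

#' Phase-randomized null distribution of shift/scale R^2
#'
#' Per iteration every channel of the specific model has its Fourier phases
#' randomized (amplitude spectra preserved, so high R^2 driven purely by
#' matching power at low frequencies survives in the null while the temporal
#' alignment is destroyed) and [shift_scale_fit()] is rerun against the
#' general model.
#'
#' @param specific,general forward models as in [shift_scale_fit()].
#' @param n_iter number of surrogates (default 20).
#' @param seed integer RNG seed.
#' @return numeric vector of `n_iter` null R^2 values.
#' @export
phase_randomized_model_null <- function(specific, general, n_iter = 20, seed) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  Sp <- as.matrix(if (is.list(specific)) specific$weights else specific)
  vapply(seq_len(n_iter), function(i) {
    surr <- t(apply(Sp, 1, phase_randomize))
    shift_scale_fit(general, surr)$r_squared
  }, numeric(1))
}
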