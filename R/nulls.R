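#' Circular-shift null distribution of reconstruction accuracies
#'
#' Calibrates chance performance for a model band. Per iteration one circular
#' shift is drawn uniformly from `[margin, L - margin]` samples (margin =
#' the model window, excluding near-zero and near-full shifts that would
#' leak true alignment), the same shift is applied to every trial's
#' envelope, one trial is chosen at random (with replacement across
#' iterations) and left out, the model is fit on the rest, and the held-out
#' accuracy is recorded.
#'
#' @param trials list of [eeg_trial] objects.
#' @param spec a [model_spec].
#' @param n_iter number of null iterations (default 50).
#' @param seed integer RNG seed.
#' @return object of class `null_distribution`: list with `values`
#'   (Pearson r per iteration), `shifts` (samples), `test_trials`,
#'   `n_iterations`, `seed`.
#' @export
circular_shift_null <- function(trials, spec, n_iter = 50, seed) {
  stopifnot(n_iter >= 2, inherits(spec, "model_spec"))
  set.seed(seed)
  fs <- spec$eeg_rate
  margin <- round(spec$window_s * fs)
  L <- min(vapply(trials, function(tr) ncol(tr$eeg), numeric(1)))
  if (L - 2 * margin < 1) {
    stop("trials too short for any valid circular shift", call. = FALSE)
  }
  shifts <- sample.int(L - 2 * margin, n_iter, replace = TRUE) + margin - 1L
  test_ids <- sample.int(length(trials), n_iter, replace = TRUE)
  values <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    sh <- shifts[it]
    shifted <- lapply(trials, function(tr) {
      env <- if (inherits(tr$envelope, "envelope")) tr$envelope$samples else tr$envelope
      tr$envelope <- circ_shift(env, sh)
      tr
    })
    i <- test_ids[it]
    m <- fit_backward_model(shifted[-i], spec)
    values[it] <- reconstruct(m, shifted[[i]], trial_id = i)$r
  }
  structure(list(values = values, shifts = shifts, test_trials = test_ids,
                 n_iterations = n_iter, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d iterations, mean r = %.4f, sd = %.4f\n",
              x$n_iterations, mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Z-score an accuracy against a null distribution
#'
#' `z = (r_true - mean(null)) / sd(null)` with the n-1 denominator. Used to
#' make accuracies comparable across frequency bands, since the spread of
#' chance-level accuracies grows as lower frequencies enter the model.
#'
#' @param r_true observed Pearson correlation.
#' @param null a [circular_shift_null()] result (or any list with `values`).
#' @param trial_id optional identifier.
#' @return tibble row with `trial`, `r_true`, `null_mean`, `null_sd`, `z`.
#' @export
zscore_accuracy <- function(r_true, null, trial_id = NA_integer_) {
  v <- null$values
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) {
    stop("null distribution has zero spread", call. = FALSE)
  }
  tibble::tibble(trial = trial_id, r_true = r_true,
                 null_mean = mean(v), null_sd = s,
                 z = (r_true - mean(v)) / s)
}

#' Within-trial d-prime reconstruction accuracy
#'
#' Splits one trial's design-matrix rows into `n_folds` random folds (the
#' lag structure is built before sampling, so each fold is a random sampling
#' of design rows). True accuracies come from fitting on all folds but one
#' and testing on the held-out fold, repeated `n_repeats` times with fresh
#' partitions. Null accuracies come from circularly shifting the envelope
#' and testing on a random `1/n_folds` sample, `n_null` times. The
#' standardized separation is
#' `d' = (mu_true - mu_null) / sqrt((var_true + var_null) / 2)`.
#'
#' @param trial an [eeg_trial].
#' @param spec a [model_spec].
#' @param n_folds folds per partition (default 10).
#' @param n_repeats partitions for the true distribution (default 5).
#' @param n_null null iterations (default 50).
#' @param seed integer RNG seed.
#' @return tibble row with `d_prime`, `mu_true`, `mu_null`, `sd_true`,
#'   `sd_null`, `n_true`, `n_null`.
#' @export
within_trial_dprime <- function(trial, spec, n_folds = 10, n_repeats = 5,
                                n_null = 50, seed) {
  stopifnot(inherits(spec, "model_spec"), n_folds >= 2)
  set.seed(seed)
  p <- preprocess_trials(list(trial), spec)[[1]]
  pca <- fit_spatial_pca(list(p$eeg), spec$n_components)
  basis <- build_spline_basis(spec$window_s, spec$knot_rate, spec$eeg_rate)
  d <- build_trial_design(p$eeg, p$env, spec, pca, basis)
  N <- nrow(d$X)
  if (N / n_folds <= ncol(d$X)) {
    stop("folds smaller than the feature count", call. = FALSE)
  }
  fold_r <- function(X, s, test_idx) {
    w <- lstsq(X[-test_idx, , drop = FALSE], s[-test_idx])
    recon <- drop(X[test_idx, , drop = FALSE] %*% w)
    if (stats::sd(recon) < 1e-14 || stats::sd(s[test_idx]) < 1e-14) return(NA_real_)
    stats::cor(recon, s[test_idx])
  }
  true_r <- c()
  for (rep in seq_len(n_repeats)) {
    fold_of <- sample(rep_len(seq_len(n_folds), N))
    for (f in seq_len(n_folds)) {
      true_r <- c(true_r, fold_r(d$X, d$s, which(fold_of == f)))
    }
  }
  if (all(is.na(true_r))) stop("all folds degenerate", call. = FALSE)
  if (anyNA(true_r)) warning("degenerate folds skipped", call. = FALSE)
  true_r <- true_r[!is.na(true_r)]
  margin <- min(round(spec$window_s * spec$eeg_rate), floor((N - 1) / 2))
  null_r <- numeric(n_null)
  for (it in seq_len(n_null)) {
    sh <- sample.int(max(N - 2 * margin, 1), 1) + margin - 1L
    s_sh <- circ_shift(d$s, sh)
    test_idx <- sample.int(N, round(N / n_folds))
    null_r[it] <- fold_r(d$X, s_sh, test_idx)
  }
  null_r <- null_r[!is.na(null_r)]
  tibble::tibble(d_prime = dprime_from_samples(true_r, null_r),
                 mu_true = mean(true_r), mu_null = mean(null_r),
                 sd_true = stats::sd(true_r), sd_null = stats::sd(null_r),
                 n_true = length(true_r), n_null = length(null_r))
}

#' Pooled-variance d-prime between two accuracy samples
#'
#' `d' = (mean(true) - mean(null)) / sqrt((var(true) + var(null)) / 2)`;
#' positive when the true accuracies exceed the null.
#'
#' @param true_vals,null_vals numeric samples.
#' @return d-prime (scalar).
#' @export
dprime_from_samples <- function(true_vals, null_vals) {
  pooled_sd <- sqrt((stats::var(true_vals) + stats::var(null_vals)) / 2)
  (mean(true_vals) - mean(null_vals)) / pooled_sd
}
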