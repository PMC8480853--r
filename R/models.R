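#' Model specification
#'
#' Hyperparameters of the frequency-constrained reconstruction model. The
#' model window sets the maximum EEG delay and the lower edge of the nominal
#' passband (`1/window_s`); the knot rate sets the upper edge
#' (`knot_rate/2`). With 19 splines (32 Hz knots on a 500 ms window) the
#' band spans three octaves.
#'
#' @param window_s model window (maximum delay) in seconds.
#' @param knot_rate spline knot sampling rate in Hz.
#' @param n_components number of spatial principal components retained.
#' @param eeg_rate EEG sampling rate in Hz.
#' @param trim_s length-2 numeric: seconds trimmed from the start and end of
#'   every trial before fitting and testing (defaults 15.5 and 16, sized for
#'   the largest 16 s model window plus the 0.5 s pre-stimulus silence).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(window_s, knot_rate, n_components, eeg_rate,
                       trim_s = c(15.5, 16)) {
  stopifnot(window_s > 0, n_components >= 1, eeg_rate > 0,
            length(trim_s) == 2, all(trim_s >= 0))
  if (knot_rate > eeg_rate) stop("knot_rate must not exceed eeg_rate", call. = FALSE)
  structure(list(window_s = window_s, knot_rate = knot_rate,
                 n_components = as.integer(n_components),
                 eeg_rate = eeg_rate, trim_s = trim_s),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  b <- band_edges(x)
  cat(sprintf(
    "<model_spec> window %g s, knots %g Hz, %d components at %g Hz (band %.4g-%.4g Hz)\n",
    x$window_s, x$knot_rate, x$n_components, x$eeg_rate, b[1], b[2]))
  invisible(x)
}

#' Nominal passband of a model
#'
#' Lower edge is the reciprocal of the model window (set by moving-average
#' removal); upper edge is half the spline knot rate (the lowpass limit of
#' the basis).
#'
#' @param spec a [model_spec].
#' @return numeric length-2 vector `c(lo, hi)` in Hz.
#' @export
band_edges <- function(spec) {
  c(1 / spec$window_s, spec$knot_rate / 2)
}

#' Spatial PCA of multichannel EEG
#'
#' Principal components of channel-mean-centered EEG pooled across training
#' trials. Loadings are orthonormal; component variances are returned for
#' all channels (needed for the forward-model variance scaling) while the
#' projection keeps the top `n_components`.
#'
#' @param eeg_list list of EEG matrices (channels x time), all with the same
#'   channel count.
#' @param n_components number of components to retain.
#' @return object of class `spatial_pca` with `channel_mean`, `loadings`
#'   (channels x n_components), `component_variance` (all channels,
#'   non-increasing), `n_components`.
#' @export
fit_spatial_pca <- function(eeg_list, n_components) {
  if (!is.list(eeg_list)) eeg_list <- list(eeg_list)
  nch <- nrow(eeg_list[[1]])
  if (n_components > nch) {
    stop("n_components exceeds the channel count", call. = FALSE)
  }
  pooled <- do.call(cbind, eeg_list)           # channels x total time
  if (ncol(pooled) <= nch) {
    stop("fewer pooled samples than channels", call. = FALSE)
  }
  pc <- stats::prcomp(t(pooled), center = TRUE, scale. = FALSE)
  structure(list(channel_mean = pc$center,
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 component_variance = pc$sdev^2,
                 n_components = as.integer(n_components)),
            class = "spatial_pca")
}

# project EEG (channels x time) into retained components (components x time)
pca_transform <- function(pca, eeg) {
  t(crossprod(sweep(eeg, 1, pca$channel_mean, "-"),
              pca$loadings))
}

# per-trial design matrix and target for one trial.
# eeg/env are already moving-average filtered; returns trimmed rows.
build_trial_design <- function(eeg_f, env_f, spec, pca, basis,
                               use_splines = TRUE, zscore_design = TRUE) {
  fs <- spec$eeg_rate
  pcs <- pca_transform(pca, eeg_f)
  pcs <- t(apply(pcs, 1, function(x) {
    s <- stats::sd(x); if (!is.finite(s) || s < 1e-12) s <- 1
    (x - mean(x)) / s
  }))
  s_z <- zscore_vec(env_f, "envelope")
  # decoding direction: the EEG response trails the stimulus, so s(t) is
  # regressed on EEG at t + delay (negative lag-matrix delays)
  delays <- -model_delays_ms(spec$window_s, fs)
  Xd <- build_lag_matrix(pcs, delays, fs)
  X <- if (use_splines) spline_project(Xd, basis) else Xd
  if (zscore_design) X <- zscore_cols(X)
  attr(X, "n_components") <- nrow(pcs)
  lead <- round(spec$trim_s[1] * fs)
  trail <- round(spec$trim_s[2] * fs)
  T_ <- nrow(X)
  if (T_ - lead - trail < 0.5 * T_ || T_ - lead - trail < 2) {
    stop("trial too short after trimming", call. = FALSE)
  }
  keep <- (lead + 1L):(T_ - trail)
  list(X = X[keep, , drop = FALSE], s = s_z[keep])
}

# validate a trial list and extract filtered EEG/envelope pairs
preprocess_trials <- function(trials, spec) {
  stopifnot(length(trials) >= 1)
  fs <- spec$eeg_rate
  lapply(trials, function(tr) {
    stopifnot(inherits(tr, "eeg_trial"))
    if (!isTRUE(all.equal(tr$rate, fs))) {
      stop("trial sampling rate does not match the model spec", call. = FALSE)
    }
    env <- if (inherits(tr$envelope, "envelope")) tr$envelope$samples else tr$envelope
    if (length(env) != ncol(tr$eeg)) {
      stop("envelope and EEG lengths differ", call. = FALSE)
    }
    list(eeg = remove_moving_average(tr$eeg, spec$window_s, fs),
         env = remove_moving_average(env, spec$window_s, fs))
  })
}

#' Fit a backward (reconstruction) model
#'
#' Per training trial the EEG and envelope have the moving average of the
#' model window removed; the EEG is projected onto spatial principal
#' components fitted to the pooled training trials; components and envelope
#' are z-scored per trial; components are lagged from 0 up to the maximum
#' delay and projected onto the cubic B-spline basis; the spline design is
#' z-scored per trial; edge samples are trimmed; trials are concatenated and
#' the weights solved by ordinary least squares,
#' `w_s = (Xs' Xs)^{-1} Xs' s(t)`.
#'
#' @param train_trials list of [eeg_trial] objects.
#' @param spec a [model_spec].
#' @param use_splines logical; `FALSE` fits on raw delayed components (used
#'   for full-resolution equivalence checks).
#' @param zscore_design z-score the spline design matrix per trial (default
#'   TRUE, the standard pipeline). The z-scoring acts in whichever feature
#'   basis is in use, so exact spline/raw equivalence checks disable it.
#' @return object of class `backward_model` with `w_s`
#'   (components x splines), `w_vec`, `spec`, `pca`, `basis`, `n_train`.
#' @export
fit_backward_model <- function(train_trials, spec, use_splines = TRUE,
                               zscore_design = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  prepped <- preprocess_trials(train_trials, spec)
  pca <- fit_spatial_pca(lapply(prepped, `[[`, "eeg"), spec$n_components)
  basis <- build_spline_basis(spec$window_s, spec$knot_rate, spec$eeg_rate)
  parts <- lapply(prepped, function(p)
    build_trial_design(p$eeg, p$env, spec, pca, basis, use_splines,
                       zscore_design))
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  s <- unlist(lapply(parts, `[[`, "s"))
  if (nrow(X) <= ncol(X)) {
    stop("fewer training samples than model features", call. = FALSE)
  }
  w <- drop(lstsq(X, s))
  ns <- if (use_splines) ncol(basis$S) else nrow(basis$S)
  structure(list(w_s = matrix(w, nrow = spec$n_components, byrow = TRUE),
                 w_vec = w, spec = spec, pca = pca, basis = basis,
                 use_splines = use_splines, zscore_design = zscore_design,
                 n_train = nrow(X)),
            class = "backward_model")
}

#' @export
print.backward_model <- function(x, ...) {
  cat(sprintf("<backward_model> %d components x %d features, N = %d\n",
              nrow(x$w_s), ncol(x$w_s), x$n_train))
  print(x$spec)
  invisible(x)
}

#' Reconstruct a trial's envelope with a fitted model
#'
#' The test EEG is projected with the training PCA loadings, preprocessed
#' identically to training (per-trial z-scoring, lagging, spline projection,
#' trimming), and the envelope is reconstructed as `s'(t) = Xs w_s`.
#' Accuracy is the Pearson correlation with the true (trimmed) envelope.
#'
#' @param model a [backward_model].
#' @param trial an [eeg_trial].
#' @param trial_id identifier recorded in the result.
#' @return object of class `recon_result`: list with `trial`, `recon`
#'   (numeric reconstruction) and `r`.
#' @export
reconstruct <- function(model, trial, trial_id = NA_integer_) {
  stopifnot(inherits(model, "backward_model"))
  if (nrow(trial$eeg) != length(model$pca$channel_mean)) {
    stop("trial channel count does not match the PCA", call. = FALSE)
  }
  p <- preprocess_trials(list(trial), model$spec)[[1]]
  d <- build_trial_design(p$eeg, p$env, model$spec, model$pca, model$basis,
                          model$use_splines, model$zscore_design)
  recon <- drop(d$X %*% model$w_vec)
  r <- pearson_strict(recon, d$s)
  structure(list(trial = trial_id, recon = recon, r = r),
            class = "recon_result")
}

#' Leave-one-trial-out reconstruction accuracies
#'
#' Fits the model on all trials but one and tests on the left-out trial,
#' for every trial in turn; the PCA and all per-trial normalizations are
#' refit within every fold.
#'
#' @param trials list of [eeg_trial] objects (at least 3).
#' @param spec a [model_spec].
#' @param use_splines,zscore_design see [fit_backward_model()].
#' @return tibble with columns `trial`, `r`, and list-column `recon`.
#' @export
leave_one_out <- function(trials, spec, use_splines = TRUE,
                          zscore_design = TRUE) {
  if (length(trials) < 3) stop("need at least 3 trials", call. = FALSE)
  res <- lapply(seq_along(trials), function(i) {
    tryCatch({
      m <- fit_backward_model(trials[-i], spec, use_splines, zscore_design)
      reconstruct(m, trials[[i]], trial_id = i)
    }, error = function(e) {
      stop(sprintf("fold %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
  })
  tibble::tibble(trial = vapply(res, function(x) as.integer(x$trial), integer(1)),
                 r = vapply(res, `[[`, numeric(1), "r"),
                 recon = lapply(res, `[[`, "recon"))
}

#' Ridge-regression baseline reconstruction
#'
#' Standard regularized envelope reconstruction on raw lagged channels (no
#' PCA truncation, no splines). For every regularization value the
#' leave-one-trial-out accuracy is computed; the value with the best mean
#' held-out accuracy is selected and its per-trial accuracies returned.
#'
#' @param trials list of [eeg_trial] objects (at least 3).
#' @param window_s model window in seconds.
#' @param eeg_rate EEG sampling rate in Hz.
#' @param lambdas regularization grid (default `c(0, 10^(0:8))`).
#' @param trim_s edge trim in seconds, as in [model_spec()].
#' @return tibble with columns `trial`, `r`; attributes `lambda` (selected
#'   value) and `score_table` (tibble of mean r per lambda).
#' @export
ridge_baseline <- function(trials, window_s, eeg_rate,
                           lambdas = c(0, 10^(0:8)), trim_s = c(15.5, 16)) {
  if (length(lambdas) == 0) stop("lambda grid is empty", call. = FALSE)
  if (length(trials) < 3) stop("need at least 3 trials", call. = FALSE)
  spec <- model_spec(window_s, eeg_rate, nrow(trials[[1]]$eeg),
                     eeg_rate, trim_s)
  prepped <- preprocess_trials(trials, spec)
  fs <- eeg_rate
  delays <- -model_delays_ms(window_s, fs)
  parts <- lapply(prepped, function(p) {
    ch_z <- t(apply(p$eeg, 1, function(x) {
      s <- stats::sd(x); if (!is.finite(s) || s < 1e-12) s <- 1
      (x - mean(x)) / s
    }))
    X <- build_lag_matrix(ch_z, delays, fs)
    s_z <- zscore_vec(p$env, "envelope")
    lead <- round(trim_s[1] * fs); trail <- round(trim_s[2] * fs)
    if (nrow(X) - lead - trail < 2) {
      stop("trial too short after trimming", call. = FALSE)
    }
    keep <- (lead + 1L):(nrow(X) - trail)
    list(G = crossprod(X[keep, , drop = FALSE]),
         b = drop(crossprod(X[keep, , drop = FALSE], s_z[keep])),
         X = X[keep, , drop = FALSE], s = s_z[keep])
  })
  Gtot <- Reduce(`+`, lapply(parts, `[[`, "G"))
  btot <- Reduce(`+`, lapply(parts, `[[`, "b"))
  p_ <- ncol(Gtot)
  rmat <- matrix(NA_real_, length(trials), length(lambdas))
  for (i in seq_along(trials)) {
    A0 <- Gtot - parts[[i]]$G
    rhs <- btot - parts[[i]]$b
    for (j in seq_along(lambdas)) {
      A <- A0 + diag(lambdas[j], p_)
      w <- if (lambdas[j] == 0) {
        drop(spd_solve(A, rhs))            # warns and falls back if singular
      } else drop(solve(A, rhs))
      recon <- drop(parts[[i]]$X %*% w)
      rmat[i, j] <- pearson_strict(recon, parts[[i]]$s)
    }
  }
  mean_r <- colMeans(rmat)
  jbest <- which.max(mean_r)
  out <- tibble::tibble(trial = seq_along(trials), r = rmat[, jbest])
  attr(out, "lambda") <- lambdas[jbest]
  attr(out, "score_table") <- tibble::tibble(lambda = lambdas, mean_r = mean_r)
  out
}

#' Hyperparameter grid search
#'
#' Evaluates the mean leave-one-trial-out accuracy for every combination of
#' model window, knot rate, and component count; ties are broken towards the
#' simplest model (fewer components, then fewer splines).
#'
#' @param trials list of [eeg_trial] objects.
#' @param windows_s numeric vector of model windows in seconds.
#' @param knot_rates numeric vector of knot rates in Hz.
#' @param n_components integer vector of component counts.
#' @param eeg_rate EEG sampling rate in Hz.
#' @param trim_s edge trim in seconds.
#' @return list with `best` (a [model_spec]) and `scores` (tibble with one
#'   row per grid cell and column `mean_r`).
#' @export
grid_search <- function(trials, windows_s, knot_rates, n_components,
                        eeg_rate, trim_s = c(15.5, 16)) {
  grid <- expand.grid(window_s = windows_s, knot_rate = knot_rates,
                      n_components = n_components)
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  mean_r <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- model_spec(grid$window_s[i], grid$knot_rate[i],
                       grid$n_components[i], eeg_rate, trim_s)
    mean(leave_one_out(trials, spec)$r)
  }, numeric(1))
  scores <- tibble::as_tibble(grid)
  scores$n_splines <- round(scores$window_s * scores$knot_rate) + 3
  scores$mean_r <- mean_r
  ord <- order(-scores$mean_r, scores$n_components, scores$n_splines)
  best_row <- scores[ord[1], ]
  best <- model_spec(best_row$window_s, best_row$knot_rate,
                     best_row$n_components, eeg_rate, trim_s)
  list(best = best, scores = scores)
}

#' Transform a backward model into a forward model
#'
#' Computes `a_s = (1/N) (Xs' Xs) w_s` on the training design, converts the
#' spline weights to delays (`w_d = S a_s`) per component, rescales each
#' component by the ratio of its variance to the summed variance across all
#' components (undoing the per-trial z-scoring and normalizing EEG variance
#' across frequency ranges), and maps components back to channels through
#' the PCA loadings. The result is interpretable as the spatiotemporal
#' evoked response implied by the decoder.
#'
#' @param model a [backward_model].
#' @param train_trials the trials the model was trained on.
#' @return object of class `forward_model`: list with `weights`
#'   (channels x delays), `delays_s`, `spec`.
#' @export
backward_to_forward <- function(model, train_trials) {
  stopifnot(inherits(model, "backward_model"))
  spec <- model$spec
  prepped <- preprocess_trials(train_trials, spec)
  parts <- lapply(prepped, function(p)
    build_trial_design(p$eeg, p$env, spec, model$pca, model$basis,
                       model$use_splines, model$zscore_design))
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  if (ncol(X) != length(model$w_vec)) {
    stop("training design does not match the model dimensions", call. = FALSE)
  }
  a_vec <- drop(crossprod(X) %*% model$w_vec) / nrow(X)
  k <- spec$n_components
  a_s <- matrix(a_vec, nrow = k, byrow = TRUE)
  w_d <- if (model$use_splines) weights_to_delays(a_s, model$basis) else a_s
  lam <- model$pca$component_variance
  ratio <- lam[seq_len(k)] / sum(lam)
  weights <- model$pca$loadings %*% (w_d * ratio)
  structure(list(weights = weights, delays_s = model$basis$delays_s,
                 spec = spec), class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %d channels x %d delays (0-%g ms)\n",
              nrow(x$weights), ncol(x$weights),
              1000 * max(x$delays_s)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a backward model's weights
#' @param x a [backward_model].
#' @param ... unused.
#' @return tibble with columns `component`, `feature`, `weight`.
#' @export
tidy.backward_model <- function(x, ...) {
  k <- nrow(x$w_s); ns <- ncol(x$w_s)
  tibble::tibble(component = rep(seq_len(k), each = ns),
                 feature = rep(seq_len(ns), times = k),
                 weight = as.vector(t(x$w_s)))
}

#' One-row model summary
#' @param x a [backward_model].
#' @param ... unused.
#' @return tibble with the hyperparameters, nominal band and sample count.
#' @export
glance.backward_model <- function(x, ...) {
  b <- band_edges(x$spec)
  tibble::tibble(window_s = x$spec$window_s, knot_rate = x$spec$knot_rate,
                 n_components = x$spec$n_components,
                 n_splines = ncol(x$w_s), band_lo_hz = b[1], band_hi_hz = b[2],
                 n_train = x$n_train)
}

#' Tidy a forward model
#' @param x a [forward_model].
#' @param ... unused.
#' @return tibble with columns `channel`, `delay_s`, `weight`.
#' @export
tidy.forward_model <- function(x, ...) {
  ch <- rownames(x$weights)
  if (is.null(ch)) ch <- as.character(seq_len(nrow(x$weights)))
  tibble::tibble(channel = rep(ch, times = ncol(x$weights)),
                 delay_s = rep(x$delays_s, each = nrow(x$weights)),
                 weight = as.vector(x$weights))
}
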