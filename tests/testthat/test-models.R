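test_that("moving-average removal zeroes constants and passes full-period sinusoids", {
  fs <- 50
  expect_true(all(abs(remove_moving_average(rep(3.7, 500), 0.5, fs)) < 1e-12))

  # sinusoid with period exactly the window: interior samples unchanged
  t <- (0:(fs * 20 - 1)) / fs
  x <- sin(2 * pi * 2 * t)          # period 0.5 s = window
  y <- remove_moving_average(x, 0.5, fs)
  interior <- 100:(length(x) - 100)
  expect_lt(max(abs(y[interior] - x[interior])), 1e-10)

  # DC + slow sinusoid: DC removed, attenuation matches the frequency
  # response |1 - Dirichlet| of the n-sample mean (odd n avoids phase terms)
  f0 <- 1 / (2 * 0.5)
  x2 <- 2 + sin(2 * pi * f0 * t)
  y2 <- remove_moving_average(x2, 0.5, fs)   # n = 25, odd
  n <- round(0.5 * fs)
  gain_theory <- abs(1 - sin(pi * f0 * n / fs) / (n * sin(pi * f0 / fs)))
  expect_lt(abs(mean(y2[interior])), 1e-3)
  expect_equal(max(abs(y2[interior])), gain_theory, tolerance = 0.01)

  expect_error(remove_moving_average(rnorm(10), 1, 50), "longer")
})

test_that("spatial PCA matches an eigendecomposition oracle", {
  set.seed(8)
  base <- rnorm(500)
  eeg <- rbind(base, base * 2, rnorm(500))    # ch1 and ch2 perfectly correlated
  pca <- fit_spatial_pca(list(eeg), 3)
  expect_lt(max(abs(crossprod(pca$loadings) - diag(3))), 1e-8)
  expect_true(all(diff(pca$component_variance) <= 1e-10))
  # two correlated channels collapse onto one component
  expect_gt(pca$component_variance[1] / sum(pca$component_variance), 0.7)
  expect_lt(pca$component_variance[3] / sum(pca$component_variance), 1e-10)

  eeg2 <- matrix(rnorm(4 * 300), 4)
  pca2 <- fit_spatial_pca(list(eeg2), 4)
  ev <- eigen(cov(t(eeg2)), symmetric = TRUE)$values
  expect_equal(pca2$component_variance, ev, tolerance = 1e-8)
  expect_error(fit_spatial_pca(list(eeg2), 5), "channel")
})

test_that("noiseless in-span tracking is reconstructed near-perfectly", {
  # one channel group carries the band-limited envelope at lag 0
  fs <- 64
  kernel <- matrix(0, 8, 1); kernel[, 1] <- seq(1, 0.5, length.out = 8)
  cfg <- synth_config(n_channels = 8, eeg_rate = fs, duration_s = 60,
                      kernel = kernel, snr = Inf, envelope_kind = "flat")
  trials <- synth_trialset(cfg, 4, seed = 9)
  spec <- model_spec(0.5, 32, 4, fs, trim_s = c(2, 2))
  m <- fit_backward_model(trials[-1], spec)
  res <- reconstruct(m, trials[[1]], trial_id = 1)
  expect_gt(res$r, 0.99)
  expect_true(res$r <= 1 && res$r >= -1)
})

test_that("an envelope independent of the EEG reconstructs at chance", {
  trials <- std_trials()
  spec <- std_spec()
  rs <- vapply(1:6, function(s) {
    set.seed(1000 + s)
    tr <- trials
    for (i in seq_along(tr)) tr[[i]]$envelope <- rnorm(ncol(tr[[i]]$eeg))
    m <- fit_backward_model(tr[-1], spec)
    reconstruct(m, tr[[1]])$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  expect_true(all(abs(rs) < 0.2))
})

test_that("degenerate targets and zero-weight models are rejected", {
  trials <- std_trials()
  spec <- std_spec()
  tr <- trials
  tr[[1]]$envelope <- rep(0, ncol(tr[[1]]$eeg))
  expect_error(fit_backward_model(tr[1], spec), "zero variance")

  m <- fit_backward_model(trials[-1], spec)
  m$w_vec <- 0 * m$w_vec
  expect_error(reconstruct(m, trials[[1]]), "zero-variance")
})

test_that("reconstruction is exactly invariant to global rescaling of test EEG", {
  trials <- std_trials()
  spec <- std_spec()
  m <- fit_backward_model(trials[-1], spec)
  r1 <- reconstruct(m, trials[[1]])$r
  scaled <- trials[[1]]
  scaled$eeg <- scaled$eeg * 3.7
  r2 <- reconstruct(m, scaled)$r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("leave-one-out returns one result per trial, order-equivariantly", {
  trials <- std_trials()
  spec <- std_spec()
  loo <- leave_one_out(trials, spec)
  expect_equal(nrow(loo), length(trials))
  expect_true(all(loo$r >= -1 & loo$r <= 1))
  # statistically identical trials: accuracies within a narrow range
  expect_lt(diff(range(loo$r)), 0.05)
  # permuting the trials permutes the results
  perm <- c(3, 1, 5, 2, 4)
  loo_p <- leave_one_out(trials[perm], spec)
  expect_equal(loo_p$r, loo$r[perm], tolerance = 1e-10)
  expect_error(leave_one_out(trials[1:2], spec), "3 trials")
})

test_that("the spline-feature OLS equals ridge at lambda = 0 and the baseline tracks", {
  trials <- fixture("small_trials", function() {
    synth_trialset(synth_config(n_channels = 4, eeg_rate = 32,
                                duration_s = 30, snr = 10,
                                kernel = synth_kernel(4, 32),
                                envelope_kind = "flat"), 4, seed = 12)
  })
  rb <- suppressWarnings(
    ridge_baseline(trials, 0.5, 32, lambdas = c(0, 1, 100, 1e4, 1e8),
                   trim_s = c(1, 1)))
  st <- attr(rb, "score_table")
  expect_equal(nrow(st), 5)
  # strong shrinkage collapses accuracy; the baseline finds signal
  expect_gt(max(st$mean_r), 0.5)
  expect_lt(st$mean_r[st$lambda == 1e8], max(st$mean_r))
  # paired comparison: best-lambda ridge r within sampling error of the
  # PCA+spline model at matched band
  spec <- model_spec(0.5, 16, 4, 32, trim_s = c(1, 1))
  loo <- leave_one_out(trials, spec)
  expect_lt(abs(mean(rb$r) - mean(loo$r)), 0.15)
  expect_error(ridge_baseline(trials, 0.5, 32, lambdas = numeric(0)), "empty")
})

test_that("grid search scores every cell and prefers knot rates covering the kernel band", {
  trials <- fixture("small_trials", function() {
    synth_trialset(synth_config(n_channels = 4, eeg_rate = 32,
                                duration_s = 30, snr = 10,
                                kernel = synth_kernel(4, 32),
                                envelope_kind = "flat"), 4, seed = 12)
  })
  # single-cell grid returns that cell
  g1 <- grid_search(trials, 0.5, 16, 2, 32, trim_s = c(1, 1))
  expect_equal(nrow(g1$scores), 1)
  expect_equal(g1$best$knot_rate, 16)

  # kernel band-limited below 8 Hz: knot rate of at least 16 Hz is selected
  # (knot rate 32 = eeg rate triggers the documented pseudo-inverse warning)
  g <- suppressWarnings(
    grid_search(trials, 0.5, c(8, 16, 32), c(2, 4), 32, trim_s = c(1, 1)))
  expect_equal(nrow(g$scores), 6)
  expect_gte(g$best$knot_rate, 16)
  expect_error(grid_search(trials, numeric(0), 16, 2, 32), "empty")
})

test_that("forward models recover the generating kernel, monotonically in SNR", {
  spec <- std_spec()
  basis <- build_spline_basis(0.5, 32, 64)
  rec_cor <- vapply(c(0.2, 1, 10), function(snr) {
    trials <- if (snr == 10) std_trials() else
      synth_trialset(std_config(snr = snr), 5, seed = 42)
    m <- fit_backward_model(trials, spec)
    fm <- backward_to_forward(m, trials)
    kbl <- bandlimit_kernel(trials[[1]]$kernel, basis)
    fw <- fm$weights - rowMeans(fm$weights)
    cor(as.vector(fw), as.vector(kbl))
  }, numeric(1))
  expect_gt(rec_cor[3], 0.9)     # SNR 10
  expect_gt(rec_cor[2], 0.5)     # SNR 1
  expect_true(all(diff(rec_cor) > -0.02))  # monotone up to estimation noise

  # zero backward weights give a zero forward model
  trials <- std_trials()
  m0 <- fit_backward_model(trials, spec)
  m0$w_vec <- 0 * m0$w_vec
  fm0 <- backward_to_forward(m0, trials)
  expect_true(all(fm0$weights == 0))
})

test_that("tidy and glance summarize fitted models", {
  trials <- std_trials()
  m <- fit_backward_model(trials[-1], std_spec())
  td <- tidy(m)
  expect_equal(nrow(td), 8 * 19)
  gl <- glance(m)
  expect_equal(gl$n_splines, 19)
  expect_equal(gl$band_lo_hz, 2)
  expect_equal(gl$band_hi_hz, 16)
  fm <- backward_to_forward(m, trials[-1])
  expect_equal(nrow(tidy(fm)), nrow(fm$weights) * ncol(fm$weights))
})
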