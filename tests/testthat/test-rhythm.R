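test_that("reconstruction spectra behave like Welch estimates", {
  fs <- 64
  t <- (0:(fs * 60 - 1)) / fs
  p <- reconstruction_psd(sin(2 * pi * 3 * t), fs, window_s = 10)
  expect_equal(p$freq[which.max(p$power)], 3)
  expect_true(all(reconstruction_psd(numeric(fs * 60), fs)$power == 0))
  set.seed(18)
  x <- rnorm(fs * 60)
  pn <- reconstruction_psd(x, fs, window_s = 10)
  expect_lt(abs(mean(pn$power) * fs / 2 - var(x)) / var(x), 0.1)
})

test_that("null spectra preserve single-subject power and attenuate coherent peaks", {
  fs <- 64
  set.seed(19)
  x <- rnorm(fs * 120)
  true_psd <- reconstruction_psd(x, fs)
  ns1 <- null_spectra(list(x), fs, n_iter = 1, seed = 20)
  expect_length(ns1, 1)
  # one subject: phase randomization preserves total power
  expect_lt(abs(sum(ns1[[1]]$power) - sum(true_psd$power)) / sum(true_psd$power),
            0.1)

  # coherent sinusoid across subjects: incoherent averaging divides its
  # peak power by about the number of subjects
  nsub <- 8
  t <- (0:(fs * 120 - 1)) / fs
  shared <- sin(2 * pi * 4 * t)
  recons <- lapply(1:nsub, function(i) shared + 0.3 * rnorm(length(t)))
  avg <- Reduce(`+`, recons) / nsub
  p_true <- reconstruction_psd(avg, fs)
  nulls <- null_spectra(recons, fs, n_iter = 60, seed = 21)
  peak_bin <- which.max(p_true$power)
  null_peak <- mean(vapply(nulls, function(p) p$power[peak_bin], numeric(1)))
  ratio <- p_true$power[peak_bin] / null_peak
  expect_gt(ratio, nsub / 2)
  expect_lt(ratio, nsub * 2)
  expect_true(all(vapply(nulls, function(p) all(p$power >= 0), logical(1))))
  expect_error(null_spectra(list(rnorm(100), rnorm(99)), fs, 2, 1), "unequal")
})

test_that("adjusted spectra subtract the noise floor bin-wise", {
  fs <- 64
  set.seed(22)
  x <- rnorm(fs * 60)
  p <- reconstruction_psd(x, fs)
  expect_true(all(adjust_psd(p, list(p, p))$adjusted == 0))
  # linearity
  p2 <- power_spectrum(p$freq, 2 * p$power)
  adj <- adjust_psd(p2, list(p))
  expect_equal(adj$adjusted, 2 * p$power - p$power)
  expect_error(adjust_psd(p, list(power_spectrum(p$freq + 0.01, p$power))),
               "grid")

  # fully incoherent multi-subject noise: adjusted ~ 0 per bin on average
  recons <- lapply(1:6, function(i) rnorm(fs * 120))
  avg <- Reduce(`+`, recons) / 6
  p_true <- reconstruction_psd(avg, fs)
  nulls <- null_spectra(recons, fs, n_iter = 50, seed = 23)
  adj2 <- adjust_psd(p_true, nulls)
  null_sd <- apply(vapply(nulls, function(p) p$power, numeric(length(p_true$freq))),
                   1, sd)
  se <- null_sd / sqrt(length(nulls))
  expect_lt(abs(mean(adj2$adjusted)), 2 * mean(se))
})

test_that("tempo estimation is exact, robust, and stable under jitter", {
  expect_equal(tempo_from_beats(c(0, 0.5, 1, 1.5)), 2)
  # one outlier interval among 20 regular ones
  beats <- cumsum(c(0, rep(0.5, 20)))
  beats[10:21] <- beats[10:21] + 0.4       # one long gap
  expect_equal(tempo_from_beats(beats), 2)
  expect_error(tempo_from_beats(c(0, 1)), "3 beats")
  expect_error(tempo_from_beats(c(0, 1, 0.5)), "increasing")
  set.seed(24)
  for (i in 1:5) {
    jit <- cumsum(rep(0.5, 40) + rnorm(40, 0, 0.025))
    expect_lt(abs(tempo_from_beats(jit) - 2) / 2, 0.02)
  }
})

test_that("tempo-multiple peaks search an inclusive +/-8% window across spectra", {
  f <- seq(0, 12, by = 0.05)[-1]
  zero <- rep(0, length(f))
  mk <- function(peak_f, h) {
    a <- zero; a[which.min(abs(f - peak_f))] <- h
    tibble::tibble(freq = f, true_psd = a, null_mean_psd = zero, adjusted = a)
  }
  # isolated peak at 2x tempo
  pk <- find_tempo_peaks(list(mk(4, 1)), tempo = 2, multiples = 1:4)
  expect_equal(pk$peak_freq[pk$multiple == 2], 4)
  # +/-8% arithmetic at m = 4, tempo 2 Hz
  expect_equal(pk$f_lo[pk$multiple == 4], 7.36)
  expect_equal(pk$f_hi[pk$multiple == 4], 8.64)

  # peak present in only one of three spectra is still found, and the
  # search is invariant to the order of the spectra
  spectra <- list(mk(2, 0.1), mk(4.1, 2), mk(6, 0.3))
  p1 <- find_tempo_peaks(spectra, 2, multiples = 2)
  p2 <- find_tempo_peaks(rev(spectra), 2, multiples = 2)
  expect_equal(p1$peak_freq, 4.1)
  expect_equal(p1$peak_power, 2)
  expect_equal(p2$peak_freq, p1$peak_freq)
  expect_equal(p2$peak_power, p1$peak_power)
  # exhaustive scan oracle over the window
  win <- f >= 0.92 * 4 & f <= 1.08 * 4
  oracle <- max(vapply(spectra, function(s) max(s$adjusted[win]), numeric(1)))
  expect_equal(p1$peak_power, oracle)

  expect_error(find_tempo_peaks(list(mk(4, 1)), tempo = 20), "cover")
})
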