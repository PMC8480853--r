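test_that("digital silence maps to the clipping floor and nonzero audio peaks at 0 dB", {
  rate <- 16000
  silent <- audio_waveform(numeric(rate), rate)
  env <- extract_envelope(silent, n_bands = 4, f_hi = 7000, out_rate = rate)
  expect_true(all(env$samples == -100))

  t <- seq(0, 2, by = 1 / rate)[-1]
  tone <- audio_waveform(0.3 * sin(2 * pi * 1000 * t), rate)
  env2 <- extract_envelope(tone, n_bands = 4, f_hi = 7000, out_rate = rate)
  expect_equal(max(env2$samples), 0)
  expect_true(all(env2$samples >= env2$floor_db))
})

test_that("a constant tone gives a flat interior envelope matching a single-band Hilbert oracle", {
  rate <- 16000
  t <- seq(0, 2, by = 1 / rate)[-1]
  x <- sin(2 * pi * 1000 * t)
  env <- extract_envelope(audio_waveform(x, rate), n_bands = 1,
                          f_lo = 500, f_hi = 2000, out_rate = rate)
  interior <- env$samples[round(0.3 * rate):round(1.7 * rate)]
  expect_lt(diff(range(interior)), 1)

  # independent oracle: analytic-signal magnitude of the gammatone-filtered
  # tone, computed from first principles with stats::fft
  fb <- gammatone_filterbank(1, 500, 2000, rate)
  h <- fb$ir[1, ]
  nfft <- stats::nextn(length(x) + length(h) - 1, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
                fft(c(h, numeric(nfft - length(h)))), inverse = TRUE))[
                  seq_along(x)] / nfft
  n <- length(y)
  hh <- numeric(n); hh[1] <- 1
  if (n %% 2 == 0) { hh[n / 2 + 1] <- 1; hh[2:(n / 2)] <- 2
  } else hh[2:((n + 1) / 2)] <- 2
  mag <- Mod(fft(fft(y) * hh, inverse = TRUE) / n)
  oracle_db <- 20 * log10(pmax(mag / max(mag), 1e-5))
  idx <- round(0.3 * rate):round(1.7 * rate)
  expect_lt(max(abs(env$samples[idx] - oracle_db[idx])), 0.1)
})

test_that("envelope is invariant to positive rescaling of the audio", {
  rate <- 8000
  set.seed(1)
  x <- rnorm(rate)
  e1 <- extract_envelope(audio_waveform(x, rate), n_bands = 4,
                         f_lo = 100, f_hi = 3000, out_rate = rate)
  e2 <- extract_envelope(audio_waveform(7.3 * x, rate), n_bands = 4,
                         f_lo = 100, f_hi = 3000, out_rate = rate)
  expect_equal(e1$samples, e2$samples, tolerance = 1e-12)
  expect_true(all(e1$samples >= e1$floor_db))
})

test_that("envelope extraction rejects bad input", {
  expect_error(audio_waveform(c(1, NaN), 100), "non-finite")
  expect_error(extract_envelope(audio_waveform(rnorm(50), 16000), n_bands = 2,
                                f_hi = 7000),
               "impulse response")
  expect_error(extract_envelope(audio_waveform(rnorm(16000), 16000),
                                f_lo = 100, f_hi = 9000), "rate/2")
})

test_that("Welch spectra locate sinusoid peaks and satisfy Parseval on noise", {
  rate <- 64
  t <- (0:(64 * rate - 1)) / rate
  env <- envelope(sin(2 * pi * 1 * t), rate, floor_db = -100)
  p <- envelope_psd(env, window_s = 16)
  expect_equal(p$freq[which.max(p$power)], 1)
  expect_true(all(diff(p$freq) > 0))
  expect_true(all(p$power >= 0))

  set.seed(2)
  noise <- envelope(rnorm(64 * rate), rate)
  pn <- envelope_psd(noise, window_s = 16)
  total <- mean(pn$power) * (rate / 2)
  expect_lt(abs(total - var(noise$samples)) / var(noise$samples), 0.1)

  z <- envelope(numeric(64 * rate), rate, floor_db = 0)
  expect_true(all(envelope_psd(z, window_s = 16)$power == 0))
  expect_error(envelope_psd(env, window_s = 0), "positive")
  expect_error(envelope_psd(env, window_s = 100), "window")
})

test_that("envelope/EEG power ratio is bin-wise division on a common grid", {
  f <- seq(0, 32, by = 0.25)[-1]
  eeg <- power_spectrum(f, rep(2, length(f)))
  env1 <- power_spectrum(f, rep(2, length(f)))
  expect_equal(envelope_eeg_power_ratio(list(env1), eeg)$power,
               rep(1, length(f)))
  env2 <- power_spectrum(f, rep(4, length(f)))
  expect_equal(envelope_eeg_power_ratio(list(env2), eeg)$power,
               rep(2, length(f)))
  # low-frequency bump against flat EEG noise: direct division oracle
  bump <- 1 + 3 * exp(-(f - 0.5)^2 / 0.1)
  env3 <- power_spectrum(f, bump)
  ratio <- envelope_eeg_power_ratio(list(env3, env3), eeg)
  expect_equal(ratio$power, bump / 2, tolerance = 1e-12)
  expect_error(envelope_eeg_power_ratio(
    list(power_spectrum(f + 1, bump)), eeg), "grid")
  expect_error(envelope_eeg_power_ratio(
    list(env1), power_spectrum(f, rep(0, length(f)))), "non-negative|zero")
})

test_that("the Fig-style normalization preset gives unit average variance", {
  rate <- 64
  set.seed(3)
  envs <- lapply(1:3, function(i)
    envelope(20 * log10(pmax(abs(rnorm(40 * rate)) * i, 1e-5)), rate))
  traces <- normalize_envelopes(envs, ma_window_s = 16)
  expect_equal(mean(vapply(traces, var, numeric(1))), 1, tolerance = 1e-10)
  eeg <- matrix(rnorm(4 * 40 * rate), 4)
  tr <- eeg_noise_trace(eeg, rate, ma_window_s = 16)
  expect_equal(sd(tr), 1, tolerance = 1e-12)
  expect_equal(mean(tr), 0, tolerance = 1e-12)
})

test_that("WAV files round-trip through the reader", {
  rate <- 8000
  set.seed(4)
  x <- 0.8 * sin(2 * pi * 440 * (0:(rate - 1)) / rate) + 0.05 * rnorm(rate)
  x <- pmax(pmin(x, 1), -1)
  path <- tempfile(fileext = ".wav")
  write_wav_pcm16(x, rate, path)
  wav <- read_wav(path)
  expect_equal(wav$rate, rate)
  expect_equal(wav$samples, x, tolerance = 2^-14)
  unlink(path)
})
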