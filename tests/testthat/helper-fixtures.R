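# Shared synthetic fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# standard study conditions: 16 channels, 64 Hz, 60 s, strong tracking
std_config <- function(snr = 10, kind = "flat") {
  synth_config(n_channels = 16, eeg_rate = 64, duration_s = 60,
               snr = snr, envelope_kind = kind)
}

std_trials <- function() {
  fixture("std_trials", function() synth_trialset(std_config(), 5, seed = 42))
}

# matching spec; trim margins scaled to the short synthetic trials
std_spec <- function(n_components = 8) {
  model_spec(0.5, 32, n_components, 64, trim_s = c(2, 2))
}

# band-limit a ground-truth kernel to a model's representable subspace:
# spline least-squares smoothing over the window plus per-row centering
bandlimit_kernel <- function(kernel, basis) {
  nd <- nrow(basis$S)
  kwin <- matrix(0, nrow(kernel), nd)
  m <- min(nd, ncol(kernel))
  kwin[, seq_len(m)] <- kernel[, seq_len(m)]
  P <- basis$S %*% solve(crossprod(basis$S), t(basis$S))
  kbl <- kwin %*% t(P)
  kbl - rowMeans(kbl)
}

# minimal PCM16 mono WAV writer (test-only, independent of read_wav)
write_wav_pcm16 <- function(x, rate, path) {
  x <- pmax(pmin(x, 1), -1)
  pcm <- as.integer(round(x * (2^15 - 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
}
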