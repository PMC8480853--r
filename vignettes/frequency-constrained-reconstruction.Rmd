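---
title: "Frequency-constrained envelope reconstruction: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-constrained envelope reconstruction: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envtrack)
```

## The problem and the model

EEG recorded during listening carries a linear trace of the stimulus
envelope. A backward model reconstructs the envelope from time-lagged EEG
and scores the reconstruction by Pearson correlation on held-out trials.
Comparing such scores across stimulus types (speech vs music) is only
meaningful per frequency band, because the envelope spectra of the stimuli
differ by orders of magnitude across bands. `envtrack` builds the band
limitation into the model itself, so that one architecture with common
hyperparameters can be slid across frequencies:

* **Lower edge — moving-average removal.** Subtracting a centred moving
  average of length equal to the model window $w$ removes DC exactly and
  attenuates components below about $1/w$; a sinusoid whose period equals
  the window is untouched in the interior. Windows are truncated at the
  trial edges, which is why fitting trims edge samples (below).
* **Spatial PCA.** Channels are decorrelated by principal components fitted
  to the pooled training trials (base `prcomp`); retaining the top $m$
  components controls spatial collinearity without ridge shrinkage.
  Components and the envelope are z-scored per trial, which makes
  reconstruction exactly invariant to a global positive rescaling of the
  test EEG (an affine change per component cancels in the z-score). It is
  *not* invariant to arbitrary per-channel rescaling, which re-mixes the
  fixed training loadings.
* **Upper edge — cubic B-spline lag basis.** The lag matrix (delays $0..w$,
  sampled at the EEG rate, zero-padded at trial edges) is projected onto a
  collocation basis of cubic B-splines with evenly spaced knots at rate $k$
  spanning exactly $[0, w]$, end knots repeated to order 4. This is a
  least-squares smoother along the lag axis with a low-pass edge near
  $k/2$. The construction yields $wk + 3$ basis functions — 7, 11, 19, 35
  for 8, 16, 32, 64 Hz knots on a 500 ms window — and satisfies the
  partition of unity (rows of the collocation matrix sum to 1).
* **OLS.** After trimming, trials are concatenated and
  $w_s = (X_s^\top X_s)^{-1} X_s^\top s(t)$ is solved by a Cholesky
  factorization of the normal equations with a conditioning check; a
  rank-deficient system falls back to a minimum-norm SVD solution with a
  warning rather than an error, because the full-resolution limit
  ($k$ equal to the EEG rate) is legitimately rank-deficient and is the
  anchor for the equivalence property below.

The nominal band is $[1/w,\ k/2]$, three octaves whenever $wk = 16$
(19 splines). Driving the whole chain with white noise and regressing the
processed noise on itself (`characterize_filter()`) confirms the band
empirically: gain within ±1 dB across the passband, roughly −20 dB two
octaves below the lower edge and below −35 dB two octaves above the upper
edge for the 500 ms / 32 Hz configuration.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `window_s` | s | 0.5 | maximum EEG delay; lower band edge $1/w$ |
| `knot_rate` | Hz | 32 | spline knot rate; upper band edge $k/2$ |
| `n_components` | — | data-dependent | spatial PCs retained; the grid search pairs it with `knot_rate` |
| `trim_s` | s | c(15.5, 16) | leading/trailing samples excluded from fitting and testing |
| `n_iter` (nulls) | — | 50 | circular-shift iterations per band |

The default trim of 15.5 s leading / 16 s trailing matches scoring every
band on identical samples when the largest window in a sweep is 16 s and
recordings begin 0.5 s before the stimulus; short synthetic fixtures use
proportionally smaller margins (2 s at 60-s trials). Fitting rejects any
trial where trimming would leave fewer than half the samples. The
moving-average window during band sweeps always equals the *current* model
window, not the largest one.

## Chance levels

Chance accuracy varies strongly with band: the lower the frequencies, the
fewer effective degrees of freedom in a trial and the wider the null
distribution. `circular_shift_null()` draws one shift per iteration,
uniformly on `[margin, L − margin]` samples with margin equal to the model
window (shifts near zero or near the trial length would leak true
alignment), applies it to every trial's envelope, refits on a random
training split and records the held-out correlation. The left-out trial is
sampled with replacement across iterations. Accuracies are reported as
z-scores against this null. Over 100 independent synthetic datasets with
envelope and EEG unrelated, these z-scores have |mean| below 0.2 and a
standard deviation within [0.7, 1.3] (asserted in the test suite).

The within-trial variant splits one trial's design rows into random folds
(lags are formed before sampling, so the lag structure stays intact) and
summarizes true vs null accuracies by a pooled-variance d-prime,
$d' = (\mu_1 - \mu_0)/\sqrt{(\sigma_1^2 + \sigma_0^2)/2}$. A limitation
worth knowing: under independence the per-trial d-prime keeps unit-scale
spread no matter how many folds are drawn, because all true folds share a
single envelope alignment whose spurious cross-validated correlation acts
as a per-realization offset; only its average across trials is calibrated
to zero. Strong tracking still separates cleanly (d' above 3 vs |d'|
typically below 1 under the null).

## Forward models and model comparison

Backward weights are not interpretable directly. The forward transform
$a_s = \tfrac{1}{N} X_s^\top X_s\, w_s$ (with the design z-scored and the
envelope at unit variance) equals the empirical cross-covariance between
the spline features and the envelope, which is what makes kernel recovery
work: on synthetic data generated from a known channels × delays kernel,
the forward model correlates above 0.9 with the band-limited kernel at
SNR 10 and above 0.5 at SNR 1, monotonically in SNR. Each component is
rescaled by its share of total PC variance (undoing per-trial z-scoring and
normalizing the strong frequency dependence of EEG variance) before mapping
back to channels.

Stimulus-general and stimulus-specific forward models are compared by
assuming the general model is a circularly shifted, per-channel positively
scaled version of the specific one: models are centred per channel, every
integer shift of the delay axis is tried (wraparound within the window; the
search is unbounded because the window is), the per-channel scale is the
clipped closed-form slope $\max(0, \langle g_k, s\rangle / \langle g_k,
g_k\rangle)$ (no intercept, models are pre-centred), and
$R^2 = 1 - \sum \mathrm{SSE} / \sum \mathrm{SST}$ pooled over channels
selects the shift. Ties go to the smallest absolute shift, positive first.
$R^2$ may be negative and is reported as-is. The null randomizes the Fourier
phases of the specific model per channel (conjugate-symmetric draw, DC and
Nyquist fixed, amplitude spectra preserved to machine precision) and refits.

## Rhythm spectra

Reconstruction spectra use Welch's method (10 s Hamming windows, half
overlap; 16 s for stimulus envelopes). The noise floor of an
across-subject average is estimated by phase-randomizing each subject's
reconstruction independently, averaging *then* computing the spectrum
(averaging precedes the PSD), 100 times; the mean null spectrum is
subtracted bin-wise to give the adjusted PSD. Peaks are sought at 1–4× the
musical tempo (the inverse median inter-beat interval, robust to occasional
missed beats) in windows of ±8% around each multiple, endpoints inclusive;
when several bins tie, the lowest frequency wins, deterministically.

## The synthetic generator

`synth_trialset()` emulates the generative assumption behind envelope
tracking: each channel is the (z-scored, dB) envelope convolved with a
known kernel plus $1/f^\alpha$ noise scaled to an exact per-channel
signal-to-noise variance ratio. The default kernel is a difference of
gammas (peak near 100 ms, trough near 200 ms) with a smooth amplitude
gradient across channels; defaults are 16 channels, 64 Hz, 60 s trials,
$\alpha = 1$. Envelope kinds: `sparse` (shot-noise bursts at ~4/s with a
0.3 Hz amplitude modulation, speech-like), `periodic` (pulse train at a
tempo, with harmonics; beat times attached), `flat` (Gaussian, near-white
in the model band — used for recovery tests because its autocorrelation is
narrow). What the generator does *not* emulate: volume conduction with
realistic topographies, spatially correlated noise, artifacts (blinks,
muscle), non-stationarity, or nonlinear tracking. Passing tests therefore
demonstrate correctness of the estimation machinery under the linear
convolutional model, not performance on real recordings.

## Numerical choices and test scales

* Gammatone filterbank for envelope extraction: order-4 FIR,
  $g(t) = t^3 e^{-2\pi\,1.019\,\mathrm{ERB}(f_c)\,t}\cos(2\pi f_c t)$,
  centre frequencies in geometric progression (endpoints inclusive), unit
  gain at centre; 128 ms impulse responses. The dB conversion happens
  before polyphase resampling to the output rate, and the floor clip
  (default −100 dB) is re-applied after resampling to absorb ripple.
* Welch scaling is one-sided density: mean power × Nyquist ≈ variance for
  white noise (Parseval, asserted within 10%).
* $S^\top S$ and $X^\top X$ solves: Cholesky with conditioning check near
  1e10, SVD minimum-norm fallback (warning) — never explicit inversion.
* Pearson correlation on a zero-variance vector is an error, never a silent
  NaN; degenerate within-trial folds are skipped with a warning.
* Knot placement must divide the window exactly; the error names the
  nearest valid knot rate.
* Test problem sizes were fixed once at desk scale: 16 channels × 64 Hz ×
  60 s × 5 trials for tracking and recovery properties; 4 channels × 32 Hz
  × 30 s × 4 trials × 100 datasets for null calibration; these sizes give
  comfortable margins on every asserted property while keeping the suite
  fast.

## Known limitations

* The exact gammachirp parameterization of the auditory filterbank is not
  specified by its common citations; the gammatone approximation here has
  no chirp term, and envelope tests avoid depending on the fine filter
  shape beyond a single-band Hilbert oracle tolerance.
* Per-channel (as opposed to global) rescaling of test EEG changes
  reconstructions, as discussed above.
* The within-trial d-prime's per-trial spread under the null (see above).
* The RDS trial container is R-native; interchange with other ecosystems
  goes through the CSV/WAV interfaces.
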