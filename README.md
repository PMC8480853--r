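# envtrack

Frequency-constrained reconstruction of auditory stimulus envelopes from
multichannel EEG.

When people listen to speech or music, scalp EEG tracks the slow amplitude
contour (the envelope) of the sound. Comparing that tracking across stimulus
types is confounded by their very different envelope spectra: a decoder that
is free to use any frequency will lean on whichever band the stimulus
happens to modulate most. `envtrack` is for auditory/EEG researchers who
want that comparison done per frequency band with one fixed model
architecture, plus honest chance levels and interpretable response
topographies.

## The model

The backward (reconstruction) model estimates the dB envelope *s(t)* from
time-lagged EEG. For each trial:

1. the moving average over the model window *w* is subtracted from the EEG
   and the envelope (high-pass at ~1/*w*);
2. the EEG is projected onto spatial principal components (PCA fitted to the
   pooled training trials) and each component is z-scored per trial;
3. each component is delayed from 0 up to *w* and the lag matrix *X_d* is
   projected onto a cubic B-spline collocation basis *S* (evenly spaced
   knots at rate *k*, end knots repeated to order 4):
   *X_s = X_d S (SᵀS)⁻¹* — a low-pass in the lag dimension at ~*k*/2;
4. edge samples are trimmed, trials concatenated, and the weights solved by
   ordinary least squares: *w_s = (X_sᵀX_s)⁻¹ X_sᵀ s(t)*.

The architecture therefore confines the reconstruction to the nominal band
[1/*w*, *k*/2]. A 500 ms window with knots at 32 Hz (19 basis splines) spans
2–16 Hz, three octaves; scaling *w* while keeping 19 splines slides that
band across frequencies (31.25 ms ... 16 s covers 32–256 Hz down to
0.0625–0.5 Hz).

Accuracy is the Pearson correlation between the reconstruction and the true
envelope on a left-out trial. Chance level is calibrated by circular-shift
nulls (envelopes rotated in time, the same shift for every trial) and
accuracies are z-scored against that null. Backward weights are transformed
into a forward model *a_s = (1/N) X_sᵀX_s w_s*, converted to delays
(*w_d = S a_s*), rescaled by each component's variance share and mapped back
to channels — a spatiotemporal evoked-response estimate. Stimulus-general
vs stimulus-specific forward models are compared by an exhaustive circular
shift with per-channel non-negative scaling (R² over channels, with
phase-randomized nulls), and reconstruction spectra are tested at 1–4× the
musical tempo (±8%) against phase-randomized noise floors.

A synthetic-data generator (`synth_*`) produces EEG as a known
channels × delays kernel convolved with an envelope plus 1/f noise, so every
stage is testable with ground truth.

## Worked example

```r
library(envtrack)

cfg    <- synth_config(n_channels = 16, eeg_rate = 64, duration_s = 60,
                       snr = 10, envelope_kind = "flat")
trials <- synth_trialset(cfg, 5, seed = 42)
spec   <- model_spec(0.5, 32, 8, 64, trim_s = c(2, 2))
spec
#> <model_spec> window 0.5 s, knots 32 Hz, 8 components at 64 Hz (band 2-16 Hz)

leave_one_out(trials, spec)
#> # A tibble: 5 × 3
#>   trial     r recon
#>   <int> <dbl> <list>
#> 1     1 0.815 <dbl [3,584]>
#> 2     2 0.809 <dbl [3,584]>
#> 3     3 0.813 <dbl [3,584]>
#> 4     4 0.814 <dbl [3,584]>
#> 5     5 0.802 <dbl [3,584]>

null <- circular_shift_null(trials, spec, n_iter = 50, seed = 7)
null
#> <null_distribution> 50 iterations, mean r = -0.0023, sd = 0.0174
zscore_accuracy(0.815, null, trial_id = 1)$z
#> [1] 47.1
```

Held-out accuracies around r = 0.81 against a null centred on zero with
spread 0.017: the synthetic envelope is tracked at ~47 standard deviations
above chance in the 2–16 Hz band, as expected at a signal-to-noise ratio of
10\. The forward transform of the same model recovers the generating kernel:

```r
m   <- fit_backward_model(trials, spec)
fwd <- backward_to_forward(m, trials)
fwd
#> <forward_model> 16 channels x 33 delays (0-500 ms)
autoplot(fwd)   # channel x delay image of the implied evoked response
```

A command-line interface wrapping these functions (subcommands `simulate`,
`envelope`, `fit`, `sweep`, `null`, `rhythm`, each writing a JSON manifest)
is installed at `inst/cli/envtrack`.

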