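Package: envtrack
Title: Frequency-Constrained Reconstruction of Auditory Stimulus Envelopes from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neural tracking of speech and music
    envelopes with multichannel EEG. Implements backward (reconstruction)
    models built from spatial principal components and a cubic B-spline lag
    basis, which constrain the reconstruction to a three-octave frequency
    band set by the model window and the spline knot rate. Includes dB
    envelope extraction from audio through a gammatone filterbank,
    leave-one-trial-out evaluation, a ridge-regression baseline and
    hyperparameter grid search, circular-shift null distributions and
    z-scored accuracies, within-trial d-prime, forward-model transformation
    of decoder weights, shift/scale comparison of forward models with
    phase-randomized nulls, rhythm-spectrum analysis of reconstructions
    against the musical tempo, and a synthetic-data generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    tibble,
    generics,
    ggplot2,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
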