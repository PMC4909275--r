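Package: pulsewave
Title: Adaptive Non-Harmonic Modeling of Pulse Wave Signals by
    Synchrosqueezing and Wave-Shape Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models single-channel arterial pulse waveforms as an amplitude-
    and frequency-modulated periodic wave-shape function, and estimates the
    model from data.  The analysis chain combines a Gaussian-window
    short-time Fourier transform, the synchrosqueezing transform for a
    sharpened time-frequency representation, penalized dynamic-programming
    ridge extraction for the instantaneous heart rate, band-limited
    reconstruction for amplitude and phase demodulation, and functional
    least-squares regression for the spectral pulse signature (the Fourier
    coefficients of the wave-shape function).  Cohort-level tools provide a
    permutation-calibrated functional ANOVA, partial-least-squares scoring
    (the global pulse signature), ROC analysis with bootstrap confidence
    intervals, and repeated leave-one-out cross-validation.  A synthetic
    pulse-cohort generator with heart-rate variability, pulsus-alternans
    style amplitude modulation and heavy-tailed ARMA noise supports
    simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    pROC,
    pracma,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
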