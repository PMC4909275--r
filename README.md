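# pulsewave

Adaptive non-harmonic modeling of arterial pulse waveforms: time-frequency
demodulation by the synchrosqueezing transform, wave-shape estimation by
functional regression, and cohort-level classification of the resulting
spectral signatures.

## Who this is for

Researchers analyzing single-channel oscillatory physiological recordings
— radial tonometry, photoplethysmography and similar pulse signals — who
want cycle-morphology features that are not confounded by heart-rate
variability (HRV) or beat-to-beat amplitude changes, and who need the
statistical machinery (functional ANOVA, PLS scoring, ROC, cross-
validation) to compare those features between groups.

## The model

A record is modeled as

```
Y(t) = A(t) · s(φ(t)) + σ(t) Φ(t)
```

where `s` is a 1-periodic unit-energy **wave-shape function** with `D = 6`
Fourier harmonics (the morphology of one pulse cycle), `φ′(t)` is the
instantaneous frequency (the beat-to-beat heart rate, ~1–1.2 Hz at rest),
`A(t)` the slowly varying amplitude, and `Φ` stationary unit-variance
noise that may be dependent and heavy-tailed.

The estimator chain: Gaussian-window STFT (σ = 0.5 s) → synchrosqueezing
(coefficients reallocated to their reassignment frequency
`ω = η − Im(V^{h′}/V)/2π`) → penalized dynamic-programming ridge = IF
trace → band reconstruction around the ridge = amplitude and phase
demodulation → least-squares regression of the record on the modulated
harmonics `Ã cos(2πℓφ̃)`, `Ã sin(2πℓφ̃)`.  The fitted coefficient vector
`γ̃ = (α̃₀, α̃₁..α̃_D, β̃₁..β̃_D)` is the **spectral pulse signature
(SPS)**; unlike a raw power spectrum it keeps the harmonic phases and is
free of HRV.  A PLS regression of group labels on SPS vectors yields the
scalar **global pulse signature (GPS)** used for classification.

## Worked example

Synthesize a 10-s, 100-Hz pulse record with ±10% sinusoidal HRV, ±8%
amplitude modulation and heavy-tailed ARMA(1,1)/t₃ noise at 0 dB, then
recover the model:

```r
library(pulsewave)

shape  <- pulse_template("control")          # six-harmonic pulse template
params <- hrv_phase(100, 10, mean_if = 1.1,
                    if_modulation = list(type = "sine", depth = 0.1,
                                         freq = 0.1,  phase = 0.4),
                    am_modulation = list(type = "sine", depth = 0.08,
                                         freq = 0.15, phase = 1.0),
                    phi0 = 0.2)
y     <- synthesize_imt(shape, params)
noisy <- add_noise_at_snr(y, arma_t_noise(1000, seed = 2), snr_db = 0)

fit <- pulse_fit(noisy)
summary(fit)
```

```
Adaptive non-harmonic pulse model
  record: 1000 samples at 100 Hz
  heart rate: 1.088 +/- 0.084 Hz
  amplitude modulation range: 0.759-0.962
  standardized SPS (D = 6):
     a0      c1      c2      c3      c4      c5      c6      d1      d2      d3 
 0.2261  1.1451  0.4950  0.0692 -0.1009 -0.0842 -0.0469  0.0000 -0.3927 -0.3670 
     d4      d5      d6 
-0.1583 -0.0408  0.0406 
  harmonic power fractions:
[1] 0.6909 0.2104 0.0735 0.0186 0.0046 0.0020
  residual sd 1.029 (design condition 2.22)
```

Despite noise as strong as the signal, the recovered heart rate (1.088 ±
0.084 Hz) matches the generator (mean 1.1 Hz, ±10% modulation), and the
standardized SPS is close to the template's coefficients
(a0 = 0.2015, c1 = 1.1514, c2 = 0.4843, d2 = −0.4080, ...).  The residual
sd ≈ 1 is the injected unit-variance noise.  `coef(fit)`, `fitted(fit)`,
`residuals(fit)`, `predict(fit, u)` (the estimated cycle shape) and
`plot(fit)` give the usual model-object views.

Cohort-level comparison:

```r
co  <- simulate_cohort(20, 20, seed = 11)     # control vs case templates
xs  <- cohort_sps(co)
an  <- cohort_analysis(xs)
an$gpf$p_value      # permutation functional ANOVA: 0.001
an$roc$auc          # training-score AUC: 1
an$roc_cv$auc       # held-out (LOOCV) AUC: 1
an$loocv$accuracy   # LOOCV accuracy over 200 repeats: 1
```

## Layout

* `R/` — wave-shape and modulation types, synthetic generators
  (`simulate_cohort`), the time-frequency stack (`stft`,
  `synchrosqueeze`, `extract_ridge`, `reconstruct_component`), wave-shape
  regression (`build_design`, `fit_sps`, `sps_standardize`), the
  `pulse_fit` model object, and cohort statistics (`gpf_test`, `fit_gps`,
  `roc_analysis`, `loocv_accuracy`).
* `vignettes/pulse-waveshape.Rmd` — the model, its assumptions, every
  tunable with units and rationale, numerical design choices, and what
  the synthetic data do and do not emulate.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
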