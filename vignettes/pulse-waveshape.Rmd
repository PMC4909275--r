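---
title: "Wave-shape analysis of pulse signals: model, estimator, design choices"
author: "pulsewave authors"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## The model

A recorded arterial pulse waveform is oscillatory but not periodic: the
beat rate drifts (heart-rate variability, HRV), the beat strength drifts
(e.g. pulsus alternans), and the recording is noisy.  `pulsewave` models a
single-channel record as

$$Y(t) = A(t)\, s(\phi(t)) + \sigma(t)\,\Phi(t),$$

where

* $s$ is the **wave-shape function** — a 1-periodic, unit-energy template
  describing what one cycle looks like, represented by a truncated Fourier
  series with cutoff $D$ (default 6 harmonics; radial-pulse harmonics above
  the sixth are negligible).  The fundamental dominates: every other
  harmonic magnitude is at most $\delta$ times the first.
* $\phi$ is a strictly increasing **phase** (in cycles); its derivative
  $\phi'(t)$ is the instantaneous frequency (IF) — the beat-to-beat heart
  rate, near 1–1.2 Hz at rest.
* $A > 0$ is the **amplitude modulation** (AM).
* Both modulations are slow: $|A'|$ and $|\phi''|$ are bounded by
  $\epsilon\,\phi'$ for a small $\epsilon$.  This regularity bound is what
  separates "shape" from "modulation" and makes the decomposition
  identifiable up to $O(\epsilon)$ perturbations.
* $\Phi$ is stationary unit-variance noise — not necessarily white or
  Gaussian.  The simulation default is ARMA(1,1)
  ($a(z) = 0.5z + 1$, $b(z) = -0.3z + 1$) driven by i.i.d. Student-$t_3$
  innovations: temporally dependent and heavy-tailed.

The target of inference is the **spectral pulse signature (SPS)**: the
$(2D+1)$-vector $\gamma = (\alpha_0, \alpha_{1..D}, \beta_{1..D})$ of
Fourier coefficients of $s$.  Unlike the classical power spectrum of the
raw record, the SPS retains the harmonic *phases* $\theta_\ell$
($\alpha_\ell = 2a_\ell\cos\theta_\ell$,
$\beta_\ell = -2a_\ell\sin\theta_\ell$), and it is estimated after the
heart-rate and amplitude variability have been demodulated away, so HRV is
not a confounder.

## The estimation chain

`pulse_fit()` runs five stages; each is exported separately.

1. **STFT** (`stft`): Gaussian window
   $h(t) = (2\pi\sigma)^{-1/2} e^{-t^2/\sigma^2}$ with $\sigma = 0.5$ s —
   long enough to see a full cycle, short enough to follow beat dynamics.
   The transform is evaluated by FFT at every sample (hop 1) on a 0–10 Hz
   grid with 0.02 Hz bins; a second transform with the differentiated
   window $h'$ feeds the reassignment operator.
2. **Synchrosqueezing** (`synchrosqueeze`): each STFT coefficient above a
   relative threshold ($10^{-4}$ of the frame maximum, guarding the
   division) is moved along the frequency axis to its reassignment
   frequency $\omega = \eta - \mathrm{Im}(V^{(h')}/V^{(h)})/2\pi$ and
   accumulated complex-valued (phase preserved) as a density on the output
   grid.  This sharpens the representation while keeping it invertible per
   frame.
3. **Ridge extraction** (`extract_ridge`): the IF curve maximizes
   $\sum_t \log |S(t, c(t))| - (\lambda/\Delta t) \sum_t (c(t{+}1)-c(t))^2$
   over the 0.5–3 Hz search band (30–180 bpm), solved exactly by dynamic
   programming.
4. **Demodulation** (`reconstruct_component`): summing the squeezed
   coefficients within ±0.25 Hz of the ridge and dividing by $h(0)$
   reconstructs the complex fundamental; the factor 2 converts the
   analytic (positive-frequency) half back to real-signal amplitude.  Its
   modulus estimates $A$, its unwrapped argument estimates $\phi$.  Both
   traces are then low-passed (below).
5. **Wave-shape regression** (`build_design`, `fit_sps`): the record is
   regressed on the $2D+1$ modulated harmonics
   $\tilde A\cos(2\pi\ell\tilde\phi)$, $\tilde A\sin(2\pi\ell\tilde\phi)$
   by QR least squares.  With exact demodulation and no noise this is
   exact (machine precision); the design Gram matrix is diagonally
   dominant whenever the phase actually advances.

```{r example}
shape <- pulse_template("control")
params <- hrv_phase(100, 10, mean_if = 1.1,
                    if_modulation = list(type = "sine", depth = 0.1,
                                         freq = 0.1, phase = 0.4),
                    am_modulation = list(type = "sine", depth = 0.08,
                                         freq = 0.15, phase = 1.0),
                    phi0 = 0.2)
y <- synthesize_imt(shape, params)
noisy <- add_noise_at_snr(y, arma_t_noise(1000, seed = 2), snr_db = 0)
fit <- pulse_fit(noisy)
summary(fit)
```

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `sigma` | 0.5 | s | window bandwidth; cycle-scale analysis |
| `half_width` | $4\sigma$ | s | Gaussian mass beyond is negligible; also the edge-trim span |
| `df` | 0.02 | Hz | oversampled binning: a 10-s record natively resolves 0.1 Hz; finer bins sharpen ridge reading without inventing resolution |
| `freq_max` | 10 | Hz | six harmonics of any ≤1.7 Hz fundamental fit below it |
| `search_band` | 0.5–3 | Hz | 30–180 beats/min |
| `lambda` | 1 | per Hz²/s | ridge curvature penalty (see below) |
| `band_hz` | 0.25 | Hz | wide enough for HRV excursions, narrow enough to exclude the 2nd harmonic |
| `smooth_hz` | 0.5 | Hz | trace smoothing cutoff (see below) |
| `D` | 6 | — | harmonic cutoff |
| `n_components` | 2 | — | PLS components for the cohort score |
| `n_perm`, `n_boot`, `n_repeats` | 999, 1000, 200 | — | permutations, bootstrap replicas, cross-validation repeats |
| `alpha` | 0.01 | — | significance level for the functional ANOVA |

## Numerical design choices

**Transform orientation.**  The STFT is computed as
$V(t,\eta) = \int f(t+u)\,h(u)\,e^{-i2\pi\eta u}\,du$, the orientation in
which a positive-frequency tone appears at positive $\eta$; the
reassignment sign is fixed by the exact identity $\omega \equiv \xi_0$ for
a tone at $\xi_0$, which the test suite asserts.  An FFT evaluates the
grid exactly (the suite compares against a direct $O(N^2)$ evaluation to
$10^{-10}$).

**Ridge penalty scaling.**  The squared-jump penalty is applied per unit
time, $(\lambda/\Delta t)(\Delta c)^2$, not per frame.  At hop 1 a frame
is 10 ms, and an unscaled per-frame penalty of order 1 is numerically
irrelevant next to log-magnitude differences, letting the ridge chase
bin-level interference wobble.  The rate form makes the penalty invariant
to the hop and gives `lambda = 1` a meaningful default; the
$\lambda \to \infty$ limit (a constant ridge at the best average bin) is
preserved and tested.

**Trace smoothing.**  With $\sigma = 0.5$ s the window's frequency
profile decays like $e^{-\pi^2\sigma^2\nu^2}$, i.e. adjacent 1-Hz-spaced
harmonics overlap at roughly half height.  The interference leaves a
ripple at cycle rate on the raw band-reconstructed amplitude and phase
(relative amplitude error ~0.13 on realistic six-harmonic shapes).  The
model itself asserts that the true modulations are slow, and the
physiological modulation bands (HRV, alternans-style AM) lie below about
0.4 Hz, so both demodulated traces are low-passed with a zero-phase
2nd-order Butterworth at 0.5 Hz — above every modulation of interest,
below any plausible fundamental.  This cuts the amplitude error to ~0.02
and the IF error to ~0.01 Hz on clean records.  Set `smooth_hz = 0` to
see the raw traces (kept as `A_raw`, `phase_raw`).

**Gauge standardization.**  The factorization $A\,s(\phi)$ leaves two
gauges free: scale can move between $A$ and $s$, and the cycle origin can
move between $\phi$ and $s$.  Demodulation lands in an arbitrary gauge
(the reconstructed amplitude absorbs the fundamental's magnitude
$2a_1$, the unwrapped phase absorbs its phase $\theta_1$).
`sps_standardize()` maps every signature to the canonical gauge — unit
template energy and $\theta_1 = 0$ — and `coef(fit)` returns that form.
Amplitude-recovery accuracy is likewise only meaningful up to a scale.

**Edges.**  The first and last window half-width (2 s) of demodulation
estimates are edge-corrupted by zero-padding and are excluded from the
regression; `fitted()`/`residuals()` return `NA` there.  Acceptance-grade
accuracy statements in the tests apply to interior frames only.

**Degenerate inputs.**  A fundamental of zero magnitude (dominance bound
undefined), non-increasing phase, IF modulation reaching the mean rate,
unit-root AR polynomials, constant-phase designs (condition number of
$cc^T$ above $10^{12}$) and single-class label vectors all raise errors;
a condition number above $10^8$ warns.  Ties in the Youden optimum take
the first maximum.

## Cohort-level statistics

`cohort_sps()` stacks standardized signatures; `cohort_analysis()` then
runs:

* **Functional ANOVA** (`gpf_test`): the pointwise one-way $F$ is summed
  across the $2D+1$ signature coordinates and calibrated by label
  permutation, $p = (1 + \#\{T^{perm} \ge T\})/(1 + n_{perm})$ — exact
  finite-sample validity with no distributional assumptions (the
  asymptotic null of the reference functional-ANOVA method is deliberately
  not used).
* **GPS scoring** (`fit_gps`): one-response NIPALS partial least squares
  of the 0/1 label on the signature matrix, folded into an affine rule
  $\hat y = \beta_0 + \gamma^\top\beta$ (the global pulse signature).  At
  full rank PLS coincides with ordinary least squares; with few
  components it is stable when $n$ is modest relative to $2D+1$.  The
  component count is deliberately exposed (`n_components`, default 2).
* **ROC** (`roc_analysis`, via pROC): trapezoidal AUC, Youden-optimal
  operating point, percentile bootstrap CI (1000 replicas).  Orientation
  is explicit: with cases coded 1, PLS scores cases higher
  (`direction = "<"`); data where cases score lower use `">"`.
* **Repeated LOOCV** (`loocv_accuracy`): per left-out record the score
  rule and its Youden threshold are refit on the remainder; the loop is
  repeated (default 200, seeded) and the spread reported — with the
  deterministic threshold rule all repeats coincide, and the loop exists
  to average any stochastic tie-breaking.  The held-out scores from the
  first repeat feed an out-of-sample ROC (`roc_cv`), because the
  training-score AUC of any fitted scoring rule is optimistically biased
  (a label-independent 40-record, 13-feature cohort shows apparent AUC
  near 0.85 but held-out AUC near 0.5).

The analysis unit is the record, not the subject.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` reproduces the statistical structure the estimator
assumes: 10-s records at 100 Hz; per-record wave shapes jittered around a
group template (coefficient sd 0.04, re-normalized); per-record mean heart
rate uniform on 1.0–1.2 Hz with ±8% sinusoidal HRV near 0.1 Hz; ±8%
sinusoidal AM near 0.15 Hz; additive ARMA(1,1)/$t_3$ noise at 0 dB.  The
two built-in templates differ mainly in relative harmonic-2–4 content
(the "case" template is the stiffer, altered waveform), with several
coefficients separated by more than three within-group standard
deviations.

It does **not** emulate: baseline wander and contact-pressure drift,
premature beats and other arrhythmic cycle-shape changes, sensor
saturation artifacts, within-record shape drift (the template is fixed
per record), or subject-level correlation between repeated records.
Passing tests therefore demonstrate correctness of the estimator under
the model's own assumptions plus heavy-tailed dependent noise — not
clinical performance on tonometry data.

## Problem sizes used in tests and the acceptance script

Single-record checks use 10-s, 100-Hz records (1000 samples; 1000 × 501
time-frequency grid).  Recovery statistics aggregate 20 independent
records; cohort checks use 20 + 20 records; the permutation-test
calibration uses 1000 null simulations at 199 permutations each; the
bootstrap CI uses 1000 replicas and cross-validation 200 repeats.  These
sizes give every stochastic assertion a comfortable margin over its
sampling noise while keeping a full run in minutes.

## Known limitations

* Single oscillatory component only; no multi-component extraction.
* First-order synchrosqueezing with the printed Gaussian window; no
  second-order or multitaper variants, no wavelet/S-transform versions.
* The reconstruction band is a fixed half-width (the theoretical
  $\epsilon^{1/3}$ band is not computable since $\epsilon$ is unknown).
* The wave shape is assumed time-invariant within a record.
* GPS components, fold-internal threshold rule and record pooling are
  configuration, not estimated from data.
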