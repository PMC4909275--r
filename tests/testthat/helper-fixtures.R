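# Shared fixture builders.  Everything is generated in code from fixed
# seeds; no data files.

fs_std <- 100
dur_std <- 10

# Random six-harmonic pulse-like shape: decaying magnitudes, progressive
# phases, moderate mean level; unit energy.
fx_shape <- function(seed) {
  withr::with_seed(seed, {
    a <- c(1, runif(1, 0.3, 0.6), runif(1, 0.15, 0.4), runif(1, 0.08, 0.25),
           runif(1, 0.04, 0.12), runif(1, 0.02, 0.06))
    th <- c(0, cumsum(runif(5, 0.4, 1.0)))
    wave_shape_harmonics(a, th, a0 = runif(1, 0.1, 0.35), normalize = TRUE)
  })
}

# Sinusoidal-HRV / sinusoidal-AM modulation traces (~±10% each).
fx_hrv <- function(seed, fs = fs_std, dur = dur_std, mean_if = NULL) {
  withr::with_seed(seed, {
    mif <- if (is.null(mean_if)) runif(1, 1.0, 1.2) else mean_if
    hrv_phase(fs, dur, mean_if = mif,
              if_modulation = list(type = "sine", depth = 0.1 * mif,
                                   freq = runif(1, 0.08, 0.15), phase = NULL),
              am_modulation = list(type = "sine", depth = 0.1,
                                   freq = runif(1, 0.1, 0.2), phase = NULL),
              phi0 = runif(1))
  })
}

fx_tone <- function(freq = 1.2, fs = fs_std, dur = dur_std) {
  t <- (0:(fs * dur - 1)) / fs
  pulse_signal(cos(2 * pi * freq * t), fs)
}

# Scale-invariant relative L2 error between an amplitude estimate and the
# true trace (the model only identifies A up to a multiplicative gauge).
am_rel_err <- function(A_hat, A_true) {
  sc <- sum(A_hat * A_true) / sum(A_hat^2)
  sqrt(mean((sc * A_hat - A_true)^2)) / sqrt(mean(A_true^2))
}

# Harmonic-amplitude relative errors of an estimated standardized SPS
# against a generator shape, restricted to harmonics carrying at least
# `min_energy` of the shape's harmonic energy.
harmonic_rel_err <- function(est, truth, min_energy = 0.05) {
  D <- (length(truth) - 1L) %/% 2L
  aT <- sqrt(truth[2:(D + 1)]^2 + truth[(D + 2):(2 * D + 1)]^2) / 2
  aE <- sqrt(est[2:(D + 1)]^2 + est[(D + 2):(2 * D + 1)]^2) / 2
  frac <- aT^2 / sum(aT^2)
  keep <- frac >= min_energy
  abs(aE - aT)[keep] / aT[keep]
}

excess_kurtosis_of <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

# Direct O(N^2) evaluation of the windowed modulated transform, the
# brute-force oracle for the FFT path.
stft_direct <- function(x, fs, window, freqs) {
  n <- length(x)
  m <- (length(window$h) - 1L) %/% 2L
  xp <- c(rep(0, m), x, rep(0, m))
  out <- matrix(0+0i, n, length(freqs))
  dt <- 1 / fs
  u <- (-m:m) * dt
  for (k in seq_len(n)) {
    seg <- xp[k:(k + 2L * m)] * window$h
    for (j in seq_along(freqs))
      out[k, j] <- sum(seg * exp(-2i * pi * freqs[j] * u)) * dt
  }
  out
}
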