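demod_of <- function(x, lambda = 1, band_hz = 0.25, smooth_hz = 0.5, ...) {
  V <- stft(x, ...)
  S <- synchrosqueeze(V)
  r <- extract_ridge(S, lambda = lambda)
  reconstruct_component(S, r, band_hz = band_hz, smooth_hz = smooth_hz)
}

test_that("a clean tone yields an exact ridge and accurate demodulation", {
  d <- demod_of(fx_tone(1.2))
  interior <- 201:800
  expect_true(all(abs(d$ridge$if_hz[interior] - 1.2) <= 0.02 + 1e-9))
  expect_true(all(d$A[interior] > 0.95 & d$A[interior] < 1.05))
  # finite difference of the unwrapped phase recovers the frequency
  fd <- diff(d$phase) * 100
  expect_true(all(abs(fd[interior] - 1.2) <= 0.02))
  expect_true(all(diff(d$phase[interior]) > 0))
  # the interior ridge of a tone is exactly flat
  expect_equal(sd(d$ridge$if_hz[interior]), 0)
  hr <- if_to_heart_rate(d$ridge)
  expect_equal(attr(hr, "mean_hz"), 1.2, tolerance = 0.05)
  expect_equal(attr(hr, "units"), "beats/s")
})

test_that("amplitude scaling is exactly linear", {
  y <- fx_tone(1.0)
  d1 <- demod_of(y)
  d3 <- demod_of(pulse_signal(3 * y$samples, y$fs))
  expect_equal(d3$A, 3 * d1$A, tolerance = 1e-12)
})

test_that("an infinite smoothness penalty forces a constant ridge", {
  s <- fx_shape(5)
  p <- fx_hrv(5)
  V <- stft(synthesize_imt(s, p), sigma = 0.5)
  S <- synchrosqueeze(V)
  r <- extract_ridge(S, lambda = 1e9)
  expect_equal(length(unique(r$if_hz)), 1L)
})

test_that("known sinusoidal IF and AM are recovered on clean records", {
  interior <- 201:800
  p <- hrv_phase(100, 10, mean_if = 1.0,
    if_modulation = list(type = "sine", depth = 0.1, freq = 0.1,
                         phase = 0.7),
    am_modulation = list(type = "sine", depth = 0.1, freq = 0.15,
                         phase = 1.3),
    phi0 = 0.2)
  s <- fx_shape(6)
  d <- demod_of(synthesize_imt(s, p))
  expect_lt(max(abs(d$if_hz[interior] - p$phiprime[interior])), 0.04)
  expect_lt(am_rel_err(d$A[interior], p$A[interior]), 0.05)
  # the IF trace's variability reflects the generator's modulation RMS
  expect_equal(sd(d$if_hz[interior]), sd(p$phiprime[interior]),
               tolerance = 0.2)
})

test_that("a lengthened cycle shows up as a locally slower heart rate", {
  # IF dips to 0.87 Hz (a 1.15-s beat) in the middle of the record
  fs <- 100
  t <- (0:999) / fs
  phiprime <- 1 - 0.13 * exp(-((t - 5) / 0.8)^2)
  phi <- cumsum(c(0, (phiprime[-1000] + phiprime[-1]) / 2 / fs))
  y <- pulse_signal(cos(2 * pi * phi), fs)
  d <- demod_of(y)
  expect_equal(min(d$if_hz[201:800]), 0.87, tolerance = 0.03)
  expect_equal(d$if_hz[which.min(abs(t - 5))], 1 / 1.15, tolerance = 0.03)
})

test_that("degenerate ridge inputs are rejected", {
  S <- synchrosqueeze(stft(fx_tone(1.2), sigma = 0.5))
  expect_error(extract_ridge(S, search_band = c(9.5, 9.51)), "bins")
  r <- extract_ridge(S)
  expect_error(reconstruct_component(S, r, band_hz = 99), "band")
})
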