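test_that("constant-rate phase generation is exact", {
  p <- hrv_phase(100, 10, mean_if = 1.3)
  expect_equal(p$phiprime, rep(1.3, 1000))
  t <- (0:999) / 100
  expect_equal(p$phi, 1.3 * t, tolerance = 1e-12)
})

test_that("sinusoidal IF modulation attains exactly the stated range", {
  p <- hrv_phase(100, 10, mean_if = 1.0,
                 if_modulation = list(type = "sine", depth = 0.1,
                                      freq = 0.1, phase = pi / 2))
  expect_equal(min(p$phiprime), 0.9, tolerance = 1e-9)
  expect_equal(max(p$phiprime), 1.1, tolerance = 1e-9)
  expect_true(all(diff(p$phi) > 0))
})

test_that("stochastic modulation is reproducible from the seed", {
  mk <- function() hrv_phase(100, 5, 1.1,
    if_modulation = list(type = "noise", depth = 0.05, cutoff = 0.2),
    am_modulation = list(type = "sine", depth = 0.08, freq = 0.15,
                         phase = NULL),
    seed = 42)
  expect_identical(mk(), mk())
})

test_that("modulation reaching the mean rate is rejected", {
  expect_error(
    hrv_phase(100, 10, 1.0,
              if_modulation = list(type = "sine", depth = 1.0, freq = 0.1,
                                   phase = 0)),
    "positive")
})

test_that("discrete regularity bound holds for an analytic fixture", {
  # phi(t) = t + 0.05 sin(2 pi 0.1 t) / (2 pi 0.1): IF = 1 + 0.05 cos(...)
  fs <- 100
  t <- (0:999) / fs
  phiprime <- 1 + 0.05 * cos(2 * pi * 0.1 * t)
  phi <- t + 0.05 * sin(2 * pi * 0.1 * t) / (2 * pi * 0.1)
  p <- imt_params(A = rep(1, 1000), phi = phi, phiprime = phiprime,
                  fs = fs, epsilon = 0.06)
  expect_lte(p$epsilon_empirical, 0.06)
  expect_error(imt_params(A = rep(1, 1000), phi = phi,
                          phiprime = phiprime, fs = fs, epsilon = 1e-6),
               "regularity")
})

test_that("generated traces satisfy their own declared bound", {
  for (seed in 1:8) {
    p <- fx_hrv(seed)
    expect_lte(p$epsilon_empirical, p$epsilon)
    expect_true(all(diff(p$phi) > 0))
  }
})

test_that("synthesis matches direct trigonometric evaluation", {
  fs <- 100
  t <- (0:999) / fs
  # pure cosine at constant 1.2 Hz
  sc <- wave_shape(alpha = c(0, 1), beta = 0)
  p <- hrv_phase(fs, 10, mean_if = 1.2)
  y <- synthesize_imt(sc, p)
  expect_equal(y$samples, cos(2 * pi * 1.2 * t), tolerance = 1e-9)

  # multi-harmonic with constant A and linear phase, against brute force
  s <- fx_shape(3)
  direct <- eval_wave_shape(s, 1.2 * t)
  expect_equal(synthesize_imt(s, p)$samples, direct, tolerance = 1e-9)

  # zero amplitude gives the zero signal
  p0 <- imt_params(A = rep(0, 1000), phi = 1.2 * t + 1e-9 * 0,
                   phiprime = rep(1.2, 1000), fs = fs)
  expect_equal(synthesize_imt(s, p0)$samples, rep(0, 1000))
})
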