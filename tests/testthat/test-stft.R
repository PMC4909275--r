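test_that("window follows the stated formula", {
  w <- gaussian_window(0.5, fs = 100)
  expect_equal(w$h0, 1 / sqrt(pi), tolerance = 1e-14)
  expect_equal(w$h[w$t == 0], w$h0)
  # symmetry and odd derivative
  expect_equal(w$h, rev(w$h))
  expect_equal(w$dh, -rev(w$dh))
  expect_equal(w$dh[w$t == 0], 0)
  # direct value at +-sigma
  expect_equal(w$h[w$t == 0.5], (2 * pi * 0.5)^(-1 / 2) * exp(-1),
               tolerance = 1e-14)
  expect_error(gaussian_window(0.5, half_width = 0.01, fs = 100),
               "half-width")
})

test_that("FFT-based transform matches the direct quadratic oracle", {
  fs <- 16
  x <- withr::with_seed(1, rnorm(64))
  w <- gaussian_window(0.4, fs = fs)
  V <- stft(x, fs = fs, window = w, freq_max = 6, df = 0.25)
  direct <- stft_direct(x, fs, w, V$freqs)
  expect_lt(max(Mod(V$values - direct)) / max(Mod(direct)), 1e-10)
  # derivative-window transform obeys the same identity
  w_d <- w
  w_d$h <- w$dh
  direct_d <- stft_direct(x, fs, w_d, V$freqs)
  expect_lt(max(Mod(V$dvalues - direct_d)) / max(Mod(direct_d)), 1e-10)
})

test_that("the transform is linear and vanishes on the zero signal", {
  fs <- 50
  x <- withr::with_seed(2, rnorm(200))
  y <- withr::with_seed(3, rnorm(200))
  args <- list(fs = fs, sigma = 0.4, freq_max = 5, df = 0.1)
  Vx <- do.call(stft, c(list(2 * x - 3 * y), args))
  Vy <- do.call(stft, c(list(x), args))
  Vz <- do.call(stft, c(list(y), args))
  expect_equal(Vx$values, 2 * Vy$values - 3 * Vz$values, tolerance = 1e-12)
  V0 <- do.call(stft, c(list(rep(0, 200)), args))
  expect_true(all(Mod(V0$values) == 0))
})

test_that("tones concentrate at their frequencies", {
  V <- stft(fx_tone(1.2), sigma = 0.5)
  interior <- 201:800
  peak <- V$freqs[apply(Mod(V$values[interior, ]), 1, which.max)]
  expect_true(all(abs(peak - 1.2) <= V$df / 2 + 1e-9))

  # sum of well-separated tones shows both ridges
  t <- (0:999) / 100
  two <- pulse_signal(cos(2 * pi * 1 * t) + 0.8 * cos(2 * pi * 3 * t), 100)
  V2 <- stft(two, sigma = 0.5)
  m <- Mod(V2$values[500, ])
  p1 <- V2$freqs[V2$freqs < 2][which.max(m[V2$freqs < 2])]
  p2 <- V2$freqs[V2$freqs > 2][which.max(m[V2$freqs > 2])]
  expect_equal(p1, 1, tolerance = 0.03)
  expect_equal(p2, 3, tolerance = 0.03)
})
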