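oracle_fit <- function(shape, params, D = 6) {
  y <- synthesize_imt(shape, params)
  design <- build_design(params$A, params$phi, D = D)
  list(y = y, design = design, sps = fit_sps(y, design))
}

test_that("design rows follow the modulated-harmonic construction", {
  p <- fx_hrv(11)
  d <- build_design(p$A, p$phi, D = 6)
  expect_equal(nrow(d$c), 13L)
  expect_equal(d$c["a0", ], p$A)
  expect_equal(d$c["c2", ], p$A * cos(2 * pi * 2 * p$phi))
  expect_equal(d$c["d5", ], p$A * sin(2 * pi * 5 * p$phi))
  expect_error(build_design(p$A[1:20], p$phi[1:20], D = 6), "few")
})

test_that("harmonic rows are orthogonal over whole periods", {
  # A = 1, phi = t over exactly 10 periods of 100 samples
  N <- 1000
  phi <- (0:(N - 1)) / 100
  d <- build_design(rep(1, N), phi, D = 3)
  G <- (d$c %*% t(d$c)) / 100          # dt * c c^T with dt = 1/100 s
  expect_equal(diag(G), c(10, rep(5, 6)), tolerance = 1e-10,
               ignore_attr = TRUE)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-10)
})

test_that("the design is diagonally dominant for non-degenerate phases", {
  for (seed in c(21, 22)) {
    p <- fx_hrv(seed)
    d <- build_design(p$A, p$phi, D = 6)
    G <- (d$c %*% t(d$c)) / p$fs
    dom <- diag(G) - (rowSums(abs(G)) - abs(diag(G)))
    expect_true(all(dom > 0))
  }
})

test_that("least squares recovers generator coefficients exactly", {
  s <- fx_shape(12)
  p <- fx_hrv(12)
  o <- oracle_fit(s, p)
  truth <- c(s$alpha, s$beta)
  expect_lt(max(abs(o$sps$gamma - truth)) / max(abs(truth)), 1e-8)
  # reconstruction reproduces the clean signal
  f_hat <- reconstruct_signal(o$sps, o$design)
  expect_lt(sqrt(mean((f_hat - o$y$samples)^2)) /
              sqrt(mean(o$y$samples^2)), 1e-8)
  # zero signal gives the zero signature
  z <- fit_sps(rep(0, 1000), o$design)
  expect_equal(unname(z$gamma), rep(0, 13))
  expect_equal(reconstruct_signal(z, o$design), rep(0, 1000))
})

test_that("coefficient errors under white noise match OLS theory", {
  s <- fx_shape(13)
  p <- fx_hrv(13)
  clean <- synthesize_imt(s, p)
  design <- build_design(p$A, p$phi, D = 6)
  truth <- c(s$alpha, s$beta)
  flags <- vapply(1:60, function(i) {
    y <- clean$samples + withr::with_seed(3000 + i, rnorm(1000))
    f <- fit_sps(y, design)
    any(abs(f$gamma - truth) > 4 * f$se)
  }, logical(1))
  # each record trips the 4-SE bound with probability well under 10%
  expect_lt(mean(flags), 0.15)
})

test_that("a constant phase is rejected as ill-conditioned", {
  d <- build_design(rep(1, 500), rep(0.3, 500), D = 2)
  expect_error(fit_sps(withr::with_seed(1, rnorm(500)), d),
               "ill-conditioned")
})

test_that("harmonic power obeys the polar identities", {
  a <- c(0.5, 0.3, 0.1)
  th <- c(0.4, 1.2, 2.0)
  s <- wave_shape_harmonics(a, th)
  expect_equal(harmonic_power(c(s$alpha, s$beta)), a^2, tolerance = 1e-12)
  expect_equal(harmonic_power(c(0, 1, 0, 0, 0, 0, 0)),
               c(1 / 4, 0, 0))
  # invariance under a per-harmonic phase rotation
  g <- withr::with_seed(9, rnorm(13))
  D <- 6
  psi <- 1.1
  z <- complex(real = g[2:7], imaginary = -g[8:13]) / 2
  zr <- z * exp(1i * psi * seq_len(D))
  g_rot <- c(g[1], 2 * Re(zr), -2 * Im(zr))
  expect_equal(harmonic_power(g_rot), harmonic_power(g), tolerance = 1e-12)
})

test_that("signatures convert back to shape samples consistently", {
  s <- fx_shape(14)
  g <- c(s$alpha, s$beta)
  u <- (0:255) / 256
  expect_equal(sps_to_shape(g, 256), eval_wave_shape(s, u),
               tolerance = 1e-12)
  expect_equal(sps_to_shape(rep(0, 13), 64), rep(0, 64))
  expect_equal(mean(sps_to_shape(g, 256)), s$alpha[1], tolerance = 1e-12)
})

test_that("standardization fixes the scale and cycle-origin gauges", {
  s <- fx_shape(15)
  g <- c(s$alpha, s$beta)
  std <- sps_standardize(g)
  # unit energy, zero first-harmonic phase
  expect_equal(std[1]^2 + sum(std[2:13]^2) / 2, 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(std[["d1"]], 0, tolerance = 1e-12)
  expect_gt(std[["c1"]], 0)
  # idempotent, scale-free, and origin-free
  expect_equal(sps_standardize(std), std, tolerance = 1e-12)
  expect_equal(sps_standardize(3.7 * g), std, tolerance = 1e-12)
  z <- complex(real = g[2:7], imaginary = -g[8:13]) / 2
  zr <- z * exp(1i * 0.77 * seq_len(6))
  g_shift <- c(g[1], 2 * Re(zr), -2 * Im(zr))
  expect_equal(sps_standardize(g_shift), std, tolerance = 1e-12)
})

test_that("signatures are invariant to the heart-rate realization", {
  s <- fx_shape(16)
  cfg <- pulse_config()
  p1 <- hrv_phase(100, 10, 1.02,
    if_modulation = list(type = "sine", depth = 0.09, freq = 0.13,
                         phase = 0.3), phi0 = 0.4)
  p2 <- hrv_phase(100, 10, 1.15,
    if_modulation = list(type = "noise", depth = 0.06, cutoff = 0.2),
    phi0 = 0.9, seed = 31)
  g1 <- coef(pulse_fit(synthesize_imt(s, p1), config = cfg))
  g2 <- coef(pulse_fit(synthesize_imt(s, p2), config = cfg))
  expect_lt(sqrt(sum((g1 - g2)^2)) / sqrt(sum(g1^2)), 0.02)
})
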