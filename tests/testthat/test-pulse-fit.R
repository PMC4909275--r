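fit_fixture <- function() {
  s <- fx_shape(30)
  p <- fx_hrv(30)
  y <- synthesize_imt(s, p)
  list(s = s, p = p, y = y, fit = pulse_fit(y))
}

test_that("the fitted-model object exposes the standard accessors", {
  fx <- fit_fixture()
  fit <- fx$fit
  expect_s3_class(fit, "pulse_fit")
  expect_length(coef(fit), 13L)
  expect_length(coef(fit, standardized = FALSE), 13L)
  f <- fitted(fit)
  r <- residuals(fit)
  expect_length(f, 1000L)
  idx <- fit$interior
  expect_equal(f[idx] + r[idx], fx$y$samples[idx], tolerance = 1e-12)
  expect_true(all(is.na(f[-idx])))
  expect_output(print(fit), "pulse model")
  expect_output(print(summary(fit)), "harmonic power")
})

test_that("predictions evaluate the estimated shape and match the truth", {
  fx <- fit_fixture()
  u <- seq(0, 1, length.out = 101)
  shat <- predict(fx$fit, u)
  struth <- eval_wave_shape(fx$s, u)
  # both are in the canonical gauge (template already standardized)
  expect_lt(sqrt(mean((shat - struth)^2)) / sqrt(mean(struth^2)), 0.05)
  expect_equal(predict(fx$fit, u), predict(fx$fit, u + 3),
               tolerance = 1e-12)
})

test_that("simulation from the fit is seeded and shaped like the record", {
  fx <- fit_fixture()
  s1 <- simulate(fx$fit, nsim = 2, seed = 5)
  s2 <- simulate(fx$fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  expect_length(s1, 2L)
  expect_length(s1[[1]]$samples, length(fx$fit$interior))
})

test_that("supplied oracle demodulation bypasses the ridge stage", {
  fx <- fit_fixture()
  fit_o <- pulse_fit(fx$y, demod = list(A = fx$p$A, phi = fx$p$phi))
  expect_null(fit_o$ridge)
  expect_true(fit_o$oracle_demod)
  truth <- c(fx$s$alpha, fx$s$beta)
  expect_lt(max(abs(fit_o$sps$gamma - truth)) / max(abs(truth)), 1e-8)
  expect_error(pulse_fit(fx$y, demod = list(A = fx$p$A[1:10],
                                            phi = fx$p$phi[1:10])),
               "grid")
})

test_that("summary reports heart-rate statistics close to the truth", {
  fx <- fit_fixture()
  sm <- summary(fx$fit)
  expect_equal(sm$heart_rate_mean, mean(fx$p$phiprime), tolerance = 0.02)
  expect_equal(sum(sm$harmonic_power), 1, tolerance = 1e-12)
})
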