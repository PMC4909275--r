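null_groups <- function(seed, n = 20, p = 13) {
  withr::with_seed(seed, list(g0 = matrix(rnorm(n * p), n),
                              g1 = matrix(rnorm(n * p), n)))
}

test_that("identical groups give zero F and p = 1", {
  g <- null_groups(1)$g0
  r <- gpf_test(g, g, n_perm = 99, seed = 2)
  expect_equal(unname(r$pointwise_f), rep(0, 13))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("a strong one-coordinate shift is detected", {
  g <- null_groups(3)
  g$g1[, 4] <- g$g1[, 4] + 3
  r <- gpf_test(g$g0, g$g1, n_perm = 999, seed = 4)
  expect_lte(r$p_value, 0.01)
  expect_equal(which.max(r$pointwise_f), 4L)
})

test_that("permutation p-values are valid and reproducible", {
  g <- null_groups(5)
  r1 <- gpf_test(g$g0, g$g1, n_perm = 199, seed = 6)
  r2 <- gpf_test(g$g0, g$g1, n_perm = 199, seed = 6)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  expect_error(gpf_test(g$g0[1, , drop = FALSE], g$g1), "two records")
})

test_that("full-rank PLS coincides with ordinary least squares", {
  d <- withr::with_seed(7, {
    X <- matrix(rnorm(40 * 5), 40)
    y <- as.integer(X[, 2] - X[, 4] + rnorm(40) > 0)
    list(X = X, y = y)
  })
  m <- fit_gps(d$X, d$y, n_components = 5)
  ols <- stats::lm(d$y ~ d$X)
  expect_equal(unname(coef(m)),
               unname(stats::coef(ols)), tolerance = 1e-8)
  expect_equal(predict(m), unname(stats::fitted(ols)), tolerance = 1e-8)
})

test_that("PLS matches the reference NIPALS implementation", {
  skip_if_not_installed("mixOmics")
  d <- withr::with_seed(8, {
    X <- matrix(rnorm(30 * 13), 30,
                dimnames = list(NULL, paste0("g", 1:13)))
    y <- rep(c(0L, 1L), 15)
    list(X = X, y = y)
  })
  m <- fit_gps(d$X, d$y, n_components = 2)
  ref <- mixOmics::pls(d$X, d$y, ncomp = 2, mode = "regression",
                       scale = FALSE)
  pred <- predict(ref, newdata = d$X)$predict[, 1, 2]
  expect_equal(predict(m), unname(pred), tolerance = 1e-8)
})

test_that("point-mass groups are ordered perfectly by the GPS", {
  X <- rbind(matrix(rep(c(1, 0, 0), each = 10), 10),
             matrix(rep(c(0, 1, 0), each = 10), 10))
  y <- rep(c(0L, 1L), each = 10)
  m <- fit_gps(X, y, n_components = 1)
  r <- roc_analysis(m$scores, y, n_boot = 0)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(fit_gps(X, rep(1L, 20)), "class")
})

test_that("ROC obeys the reversal identity and null behavior", {
  d <- withr::with_seed(9, list(s = rnorm(200),
                                y = rep(c(0L, 1L), each = 100)))
  r1 <- roc_analysis(d$s, d$y, n_boot = 0)
  r2 <- roc_analysis(-d$s, d$y, n_boot = 0)
  expect_equal(r1$auc + r2$auc, 1, tolerance = 1e-12)
  expect_gt(r1$auc, 0.35)
  expect_lt(r1$auc, 0.65)
})

test_that("the bootstrap CI brackets the AUC and is seeded", {
  d <- withr::with_seed(10, {
    y <- rep(c(0L, 1L), each = 30)
    list(s = rnorm(60) + y, y = y)
  })
  r <- roc_analysis(d$s, d$y, n_boot = 200, seed = 3)
  expect_lte(r$auc_ci[1], r$auc)
  expect_gte(r$auc_ci[2], r$auc)
  r2 <- roc_analysis(d$s, d$y, n_boot = 200, seed = 3)
  expect_identical(r$auc_ci, r2$auc_ci)
})

test_that("the internal Youden rule agrees with the pROC optimum", {
  for (seed in 11:13) {
    d <- withr::with_seed(seed, {
      y <- rep(c(0L, 1L), each = 25)
      list(s = rnorm(50) + 1.2 * y, y = y)
    })
    r <- pROC::roc(d$y, d$s, levels = c(0L, 1L), direction = "<",
                   quiet = TRUE)
    best <- pROC::coords(r, "best", best.method = "youden",
                         transpose = FALSE)[1, ]
    mine <- pulsewave:::youden_threshold(d$s, d$y, "<")
    pred_mine <- as.integer(d$s > mine)
    pred_ref <- as.integer(d$s > best$threshold)
    expect_equal(pred_mine, pred_ref)
  }
})

test_that("cross-validation separates what is separable and not more", {
  sep <- withr::with_seed(14, {
    X <- rbind(matrix(rnorm(20 * 13), 20),
               matrix(rnorm(20 * 13, mean = 2), 20))
    list(X = X, y = rep(c(0L, 1L), each = 20))
  })
  l <- loocv_accuracy(sep$X, sep$y, n_repeats = 5, seed = 1)
  expect_equal(l$accuracy, 1)
  expect_equal(l$sd, 0)           # deterministic pipeline: no spread
  nul <- withr::with_seed(15, {
    list(X = matrix(rnorm(40 * 13), 40), y = rep(c(0L, 1L), 20))
  })
  ln <- loocv_accuracy(nul$X, nul$y, n_repeats = 3, seed = 1)
  expect_gt(ln$accuracy, 0.25)
  expect_lt(ln$accuracy, 0.75)
  rcv <- roc_analysis(ln$scores, nul$y, n_boot = 0)
  expect_gt(rcv$auc, 0.3)
  expect_lt(rcv$auc, 0.7)
})
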