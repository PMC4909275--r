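#' Fit the adaptive non-harmonic model to a pulse record
#'
#' The central estimator of the package.  A single-channel pulse waveform
#' is modeled as \eqn{Y(t) = A(t)\,s(\phi(t)) + \sigma(t)\Phi(t)} with a
#' 1-periodic wave-shape function \eqn{s}, slowly varying amplitude
#' \eqn{A} and strictly increasing phase \eqn{\phi}.  The fit proceeds
#' through the full analysis chain:
#' Gaussian-window STFT, synchrosqueezing, penalized dynamic-programming
#' ridge extraction (the instantaneous heart rate), band reconstruction
#' around the ridge (amplitude and phase demodulation), and least-squares
#' wave-shape regression yielding the spectral pulse signature (SPS).
#'
#' The first and last window half-width of samples carry edge-corrupted
#' demodulation estimates and are excluded from the regression; the
#' stored `interior` index records the retained range.
#'
#' @param x a [pulse_signal()], or a numeric sample vector (then `fs` is
#'   required).
#' @param fs sampling rate in Hz for bare vectors.
#' @param config analysis settings from [pulse_config()].
#' @param demod optional externally supplied demodulation: a list with
#'   components `A` and `phi` (phase in cycles) on the signal grid, e.g.
#'   generator ground truth.  When given, the time-frequency stage is
#'   skipped and the regression uses these traces on the full record.
#' @param keep_tf keep the STFT/SST matrices in the returned object
#'   (tens of megabytes per 10-s record; off by default).
#' @return An object of class `"pulse_fit"`.  Key components: `sps` (the
#'   raw regression result, see [fit_sps()]), `sps_std` (the standardized
#'   signature, see [sps_standardize()]), `demod`, `ridge`, `interior`,
#'   `signal`, `config`.  Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`, `simulate`.
#' @examples
#' p <- hrv_phase(100, 10, mean_if = 1.1,
#'                if_modulation = list(type = "sine", depth = 0.08,
#'                                     freq = 0.1, phase = 1))
#' s <- wave_shape_harmonics(a = c(1, 0.5, 0.3), normalize = TRUE)
#' y <- synthesize_imt(s, p)
#' fit <- pulse_fit(y)
#' coef(fit)[1:4]
#' @export
pulse_fit <- function(x, fs = NULL, config = pulse_config(),
                      demod = NULL, keep_tf = FALSE) {
  sig <- as_pulse_signal(x, fs)
  stopifnot(inherits(config, "pulse_config"))
  n <- length(sig$samples)
  tf <- NULL
  ridge <- NULL
  if (is.null(demod)) {
    w <- gaussian_window(config$sigma, config$half_width, fs = sig$fs)
    V <- stft(sig, window = w, freq_max = config$freq_max, df = config$df,
              hop = config$hop)
    S <- synchrosqueeze(V, threshold = config$threshold)
    ridge <- extract_ridge(S, search_band = config$search_band,
                           lambda = config$lambda)
    dm <- reconstruct_component(S, ridge, band_hz = config$band_hz,
                                smooth_hz = config$smooth_hz)
    if (keep_tf) tf <- list(stft = V, sst = S)
    A <- dm$A
    phi <- dm$phase
    trim <- round(config$half_width * sig$fs)
    interior <- (trim + 1L):(n - trim)
  } else {
    A <- demod$A
    phi <- demod$phi
    if (length(A) != n || length(phi) != n)
      stop("supplied demodulation does not match the signal grid",
           call. = FALSE)
    dm <- structure(list(R = NULL, A = A, phase = phi,
                         times = signal_times(sig), fs = sig$fs,
                         ridge = NULL, band_hz = NA_real_),
                    class = "pulse_demod")
    interior <- seq_len(n)
  }
  design <- build_design(A[interior], phi[interior], D = config$D)
  sps <- fit_sps(sig$samples[interior], design)
  structure(list(sps = sps, sps_std = sps_standardize(sps),
                 demod = dm, ridge = ridge, interior = interior,
                 signal = sig, config = config, tf = tf,
                 oracle_demod = !is.null(demod)),
            class = "pulse_fit")
}

#' @export
print.pulse_fit <- function(x, ...) {
  cat("Adaptive non-harmonic pulse model fit\n")
  print(x$signal)
  if (!is.null(x$ridge))
    cat(sprintf("  heart rate: mean %.3f Hz, sd %.3f Hz\n",
                mean(x$ridge$if_hz), sd(x$ridge$if_hz)))
  cat(sprintf("  SPS (D = %d), residual sd %.3g\n", x$sps$D, x$sps$sigma))
  invisible(x)
}

#' @param object,x a `pulse_fit` object.
#' @param standardized return the gauge-standardized signature (the form
#'   used for cohort comparison) rather than the raw regression
#'   coefficients.
#' @param ... unused.
#' @rdname pulse_fit
#' @export
coef.pulse_fit <- function(object, standardized = TRUE, ...) {
  if (standardized) object$sps_std else object$sps$gamma
}

#' @rdname pulse_fit
#' @export
fitted.pulse_fit <- function(object, ...) {
  out <- rep(NA_real_, length(object$signal$samples))
  out[object$interior] <- object$sps$fitted
  out
}

#' @rdname pulse_fit
#' @export
residuals.pulse_fit <- function(object, ...) {
  out <- rep(NA_real_, length(object$signal$samples))
  out[object$interior] <- object$sps$residuals
  out
}

#' @rdname pulse_fit
#' @export
summary.pulse_fit <- function(object, ...) {
  hp <- harmonic_power(object$sps_std)
  out <- list(
    n = length(object$signal$samples), fs = object$signal$fs,
    D = object$sps$D,
    heart_rate_mean = if (is.null(object$ridge)) NA_real_
                      else mean(object$ridge$if_hz),
    heart_rate_sd = if (is.null(object$ridge)) NA_real_
                    else sd(object$ridge$if_hz),
    am_range = range(object$demod$A[object$interior]),
    sps = object$sps_std,
    harmonic_power = hp / sum(hp),
    residual_sd = object$sps$sigma,
    condition = object$sps$condition,
    oracle_demod = object$oracle_demod)
  class(out) <- "summary.pulse_fit"
  out
}

#' @export
print.summary.pulse_fit <- function(x, ...) {
  cat("Adaptive non-harmonic pulse model\n")
  cat(sprintf("  record: %d samples at %g Hz\n", x$n, x$fs))
  if (!is.na(x$heart_rate_mean))
    cat(sprintf("  heart rate: %.3f +/- %.3f Hz\n",
                x$heart_rate_mean, x$heart_rate_sd))
  cat(sprintf("  amplitude modulation range: %.3g-%.3g\n",
              x$am_range[1L], x$am_range[2L]))
  cat(sprintf("  standardized SPS (D = %d):\n", x$D))
  print(round(x$sps, 4))
  cat("  harmonic power fractions:\n")
  print(round(x$harmonic_power, 4))
  cat(sprintf("  residual sd %.4g (design condition %.3g)\n",
              x$residual_sd, x$condition))
  invisible(x)
}

#' @param u cycle positions at which to evaluate the estimated wave-shape
#'   function (1-periodic).
#' @rdname pulse_fit
#' @export
predict.pulse_fit <- function(object, u = seq(0, 1, length.out = 257L),
                              standardized = TRUE, ...) {
  g <- coef(object, standardized = standardized)
  D <- object$sps$D
  shape <- wave_shape(alpha = g[1L:(D + 1L)],
                      beta = g[(D + 2L):(2L * D + 1L)])
  eval_wave_shape(shape, u)
}

#' @param nsim number of synthetic records to simulate from the fitted
#'   model (estimated shape, demodulated amplitude/phase, residual noise
#'   level).
#' @param seed integer seed for the simulated noise.
#' @rdname pulse_fit
#' @export
simulate.pulse_fit <- function(object, nsim = 1, seed = NULL, ...) {
  idx <- object$interior
  clean <- object$sps$fitted
  fs <- object$signal$fs
  gen <- function() {
    lapply(seq_len(nsim), function(i) {
      pulse_signal(clean + rnorm(length(clean), sd = object$sps$sigma),
                   fs = fs, t0 = (idx[1L] - 1L) / fs)
    })
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @rdname pulse_fit
#' @export
plot.pulse_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(par(op))
  plot(x$signal, main = "record")
  if (!is.null(x$ridge))
    lines(x$ridge$times, x$ridge$if_hz, col = "grey60")
  u <- seq(0, 1, length.out = 257L)
  plot(u, predict(x, u), type = "l", xlab = "cycle position u",
       ylab = "s(u)", main = "estimated wave shape")
  invisible(x)
}
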