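#' Pulse signal container
#'
#' A uniformly sampled single-channel pulse waveform.
#'
#' @param samples numeric vector of amplitudes (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds; sample `k` (0-based) sits at
#'   `t0 + k / fs`.
#' @return An object of class `"pulse_signal"`.
#' @export
pulse_signal <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  stopifnot_scalar(fs, "fs")
  if (length(samples) < 2L)
    stop("a pulse signal needs at least two samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("pulse signal contains non-finite samples", call. = FALSE)
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "pulse_signal")
}

#' @export
print.pulse_signal <- function(x, ...) {
  cat(sprintf("Pulse signal: %d samples at %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
plot.pulse_signal <- function(x, ...) {
  plot(signal_times(x), x$samples, type = "l",
       xlab = "time (s)", ylab = "amplitude (a.u.)", ...)
  invisible(x)
}

#' Sample times of a pulse signal
#' @param x a [pulse_signal()].
#' @return Numeric vector of times in seconds.
#' @export
signal_times <- function(x) {
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

#' Amplitude and phase traces for the adaptive non-harmonic model
#'
#' Bundles sampled amplitude modulation \eqn{A(t)}, phase \eqn{\phi(t)}
#' (in cycles, strictly increasing) and instantaneous frequency
#' \eqn{\phi'(t)} (Hz) on a uniform grid, together with the regularity
#' bound \eqn{\epsilon} under which both \eqn{|A'(t)|} and
#' \eqn{|\phi''(t)|} are bounded by \eqn{\epsilon\,\phi'(t)}.  The bound is
#' verified discretely on construction.
#'
#' @param A positive numeric vector, amplitude per sample.
#' @param phi numeric vector, phase in cycles, strictly increasing.
#' @param phiprime positive numeric vector, IF in Hz.
#' @param fs sampling rate (Hz) of the common grid.
#' @param epsilon declared regularity bound; if `NULL`, the smallest bound
#'   satisfied by the discrete traces (with a 5% margin) is recorded.
#' @return An object of class `"imt_params"`.
#' @export
imt_params <- function(A, phi, phiprime, fs, epsilon = NULL) {
  A <- as.numeric(A); phi <- as.numeric(phi); phiprime <- as.numeric(phiprime)
  n <- length(phi)
  if (length(A) != n || length(phiprime) != n)
    stop("A, phi and phiprime must share one grid", call. = FALSE)
  if (any(diff(phi) <= 0)) stop("phase must be strictly increasing", call. = FALSE)
  if (any(phiprime <= 0)) stop("instantaneous frequency must be positive", call. = FALSE)
  if (any(A < 0)) stop("amplitude modulation must be non-negative", call. = FALSE)
  emp <- imt_regularity(A, phiprime, fs)
  if (is.null(epsilon)) epsilon <- 1.05 * emp
  if (emp > epsilon)
    stop(sprintf(
      "traces violate the declared regularity bound (need epsilon >= %.3g)",
      emp), call. = FALSE)
  structure(list(A = A, phi = phi, phiprime = phiprime, fs = fs,
                 epsilon = epsilon, epsilon_empirical = emp),
            class = "imt_params")
}

# Smallest epsilon satisfied by the discrete traces:
# max over interior samples of |dA/dt| / phi' and |dphi'/dt| / phi'.
imt_regularity <- function(A, phiprime, fs) {
  dA <- abs(diff(A)) * fs
  dF <- abs(diff(phiprime)) * fs
  denom <- pmin(phiprime[-1L], phiprime[-length(phiprime)])
  max(dA / denom, dF / denom)
}

#' @export
print.imt_params <- function(x, ...) {
  cat(sprintf(
    "IMT parameters: %d samples at %g Hz\n  IF %.3g-%.3g Hz, AM %.3g-%.3g, epsilon = %.3g\n",
    length(x$phi), x$fs, min(x$phiprime), max(x$phiprime),
    min(x$A), max(x$A), x$epsilon))
  invisible(x)
}

#' Generate smooth heart-rate and amplitude traces
#'
#' Produces the ground-truth modulation traces for synthetic pulse
#' records: an instantaneous-frequency trace around `mean_if` emulating
#' heart-rate variability, integrated by cumulative trapezoid to a
#' strictly increasing phase, and an amplitude trace around 1 emulating
#' slow amplitude modulation such as pulsus alternans.
#'
#' Two modulation forms are available for both IF and AM:
#' `list(type = "sine", depth =, freq =, phase =)` gives
#' \eqn{m(t) = depth \cdot \sin(2\pi\,freq\,t + phase)}; with `phase = NULL`
#' the phase is drawn uniformly.  `list(type = "noise", depth =, cutoff =)`
#' gives low-pass filtered Gaussian noise (2nd-order Butterworth, cutoff in
#' Hz) rescaled to RMS `depth`.  `list(type = "none")` disables modulation.
#'
#' @param fs sampling rate, Hz.
#' @param duration record length, seconds.
#' @param mean_if mean instantaneous frequency, Hz (about 1-1.2 Hz for
#'   resting adult pulse).
#' @param if_modulation,am_modulation modulation specifications, see
#'   Details.
#' @param phi0 initial phase in cycles.
#' @param seed integer seed; required when any modulation is stochastic.
#' @return An [imt_params()] object.
#' @examples
#' p <- hrv_phase(100, 10, mean_if = 1,
#'                if_modulation = list(type = "sine", depth = 0.1,
#'                                     freq = 0.1, phase = 0))
#' range(p$phiprime)   # exactly [0.9, 1.1]
#' @export
hrv_phase <- function(fs, duration, mean_if = 1.1,
                      if_modulation = list(type = "none"),
                      am_modulation = list(type = "none"),
                      phi0 = 0, seed = NULL) {
  stopifnot_scalar(fs, "fs"); stopifnot_scalar(duration, "duration")
  stopifnot_scalar(mean_if, "mean_if")
  n <- round(fs * duration)
  t <- (seq_len(n) - 1L) / fs
  gen <- function() {
    ifmod <- modulation_trace(if_modulation, t, fs)
    ammod <- modulation_trace(am_modulation, t, fs)
    list(ifmod = ifmod, ammod = ammod)
  }
  m <- if (is.null(seed)) gen() else with_seed(seed, gen())
  phiprime <- mean_if + m$ifmod
  if (any(phiprime <= 0))
    stop("IF modulation amplitude reaches or exceeds mean_if; ",
         "instantaneous frequency must stay positive", call. = FALSE)
  A <- 1 + m$ammod
  if (any(A <= 0))
    stop("AM modulation depth too large; amplitude must stay positive",
         call. = FALSE)
  phi <- phi0 + cumtrapz_shifted(phiprime, 1 / fs)
  imt_params(A = A, phi = phi, phiprime = phiprime, fs = fs)
}

# Trapezoid phase with phi[1] = 0.
cumtrapz_shifted <- function(y, dt) {
  as.numeric(pracma::cumtrapz(seq_along(y) * dt, y))
}

modulation_trace <- function(spec, t, fs) {
  type <- spec$type %||% "none"
  switch(type,
    none = rep(0, length(t)),
    sine = {
      ph <- spec$phase
      if (is.null(ph)) ph <- runif(1, 0, 2 * pi)
      spec$depth * sin(2 * pi * spec$freq * t + ph)
    },
    noise = {
      cutoff <- spec$cutoff %||% 0.2
      bf <- signal::butter(2, min(0.99, 2 * cutoff / fs), type = "low")
      x <- as.numeric(signal::filtfilt(bf, rnorm(length(t))))
      r <- sqrt(mean(x^2))
      if (r == 0) rep(0, length(t)) else spec$depth * x / r
    },
    stop("unknown modulation type: ", type, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize an amplitude- and frequency-modulated pulse signal
#'
#' Evaluates the adaptive non-harmonic model
#' \eqn{f(t) = A(t)\, s(\phi(t))} on the sampling grid of `params`, with
#' the 1-periodic wave-shape `s` evaluated at the phase in cycles.
#'
#' @param shape a [wave_shape()].
#' @param params an [imt_params()] object carrying \eqn{A} and \eqn{\phi}.
#' @return A [pulse_signal()].
#' @export
synthesize_imt <- function(shape, params) {
  stopifnot(inherits(shape, "wave_shape"), inherits(params, "imt_params"))
  pulse_signal(params$A * eval_wave_shape(shape, params$phi),
               fs = params$fs)
}
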