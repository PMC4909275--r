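#' Stationary ARMA noise with heavy-tailed innovations
#'
#' Simulates the noise process used in the synthetic experiments: an
#' ARMA(p, q) recursion driven by i.i.d. Student-t innovations,
#' standardized to unit sample standard deviation.  The default model is
#' ARMA(1,1) with autoregression polynomial \eqn{a(z) = 0.5 z + 1} and
#' moving-average polynomial \eqn{b(z) = -0.3 z + 1}, with \eqn{t_3}
#' innovations.  Polynomials are interpreted through the lag operator
#' \eqn{B} as \eqn{a(B)\,x = b(B)\,e}, i.e. for the default model
#' \deqn{x_k = -0.5\, x_{k-1} + e_k - 0.3\, e_{k-1}.}
#'
#' The recursion is run with a burn-in (default 500 samples, discarded)
#' and the retained stretch is divided by its sample standard deviation,
#' so the output models the unit-variance stationary process that a
#' slowly varying noise level multiplies.
#'
#' @param n number of samples to return.
#' @param ar coefficients of \eqn{a(z)} excluding the constant 1, i.e.
#'   `ar = 0.5` means \eqn{a(z) = 1 + 0.5 z}.
#' @param ma coefficients of \eqn{b(z)} excluding the constant 1.
#' @param dof degrees of freedom of the Student-t innovations; `Inf`
#'   gives Gaussian innovations.
#' @param burn_in samples discarded before the retained stretch.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n` with sample standard deviation 1.
#' @examples
#' x <- arma_t_noise(1000, seed = 1)
#' sd(x)   # exactly 1 by construction
#' @export
arma_t_noise <- function(n, ar = 0.5, ma = -0.3, dof = 3,
                         burn_in = 500L, seed = NULL) {
  stopifnot_scalar(n, "n")
  # a(B) x = b(B) e  <=>  x_k = -sum(ar_j x_{k-j}) + e_k + sum(ma_j e_{k-j}),
  # which in the convention of stats::arima.sim is ar' = -ar, ma' = ma.
  ar_sim <- -ar
  ma_sim <- ma
  if (length(ar_sim) && any(Mod(polyroot(c(1, -ar_sim))) <= 1))
    stop("non-stationary AR polynomial: roots of a(z) must lie outside ",
         "the unit disc", call. = FALSE)
  innov <- if (is.finite(dof)) {
    function(n, ...) rt(n, df = dof)
  } else {
    function(n, ...) rnorm(n)
  }
  model <- list()
  if (length(ar_sim) && any(ar_sim != 0)) model$ar <- ar_sim
  if (length(ma_sim) && any(ma_sim != 0)) model$ma <- ma_sim
  gen <- function() {
    x <- as.numeric(arima.sim(model = model, n = n, rand.gen = innov,
                              n.start = max(burn_in, 1L)))
    x / sd(x)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Add noise to a signal at an exact signal-to-noise ratio
#'
#' Rescales `noise` so that
#' \eqn{20 \log_{10}(\mathrm{sd(signal)} / \mathrm{sd(noise)})} equals
#' `snr_db` exactly, then adds it to the signal.
#'
#' @param clean a [pulse_signal()].
#' @param noise numeric vector, same length as the signal.
#' @param snr_db target signal-to-noise ratio in decibels (0 dB means
#'   noise as strong as the signal).
#' @return A [pulse_signal()] with the scaled noise added.
#' @export
add_noise_at_snr <- function(clean, noise, snr_db) {
  stopifnot(inherits(clean, "pulse_signal"))
  if (length(noise) != length(clean$samples))
    stop("noise and signal lengths differ", call. = FALSE)
  s_sd <- sd(clean$samples)
  if (s_sd == 0) stop("zero-variance signal: SNR undefined", call. = FALSE)
  n_sd <- sd(noise)
  if (n_sd == 0) stop("zero-variance noise", call. = FALSE)
  scale <- s_sd / n_sd * 10^(-snr_db / 20)
  pulse_signal(clean$samples + scale * noise, fs = clean$fs, t0 = clean$t0)
}
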