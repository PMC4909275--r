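#' Wave-shape functions
#'
#' A wave-shape function is a 1-periodic template describing how a pulse
#' waveform looks over a single cycle.  It is represented by a truncated
#' Fourier series
#' \deqn{s(u) = \alpha_0 + \sum_{\ell=1}^{D} \alpha_\ell \cos(2\pi\ell u) +
#'   \beta_\ell \sin(2\pi\ell u),}
#' with harmonic cutoff \eqn{D}.  The magnitude of the \eqn{\ell}-th
#' harmonic is \eqn{a_\ell = \sqrt{\alpha_\ell^2+\beta_\ell^2}/2}
#' (\eqn{a_0 = |\alpha_0|}), and the dominance bound \eqn{\delta} is the
#' largest ratio \eqn{a_\ell / a_1} over \eqn{\ell \neq 1}: the fundamental
#' must carry the dominant harmonic content.  The tail-energy bound
#' \eqn{\theta} is zero by construction for a finite series.
#'
#' @param alpha numeric vector of length `D + 1`; cosine coefficients
#'   \eqn{\alpha_0, \ldots, \alpha_D}.
#' @param beta numeric vector of length `D`; sine coefficients
#'   \eqn{\beta_1, \ldots, \beta_D}.
#' @param normalize logical; if `TRUE`, rescale the coefficients so the
#'   template has unit energy \eqn{\int_0^1 s(u)^2\,du = 1}.
#'
#' @return An object of class `"wave_shape"` with components `alpha`,
#'   `beta`, `D`, `delta`, `theta` (always 0) and `energy`.
#'
#' @examples
#' s <- wave_shape(alpha = c(0, 1), beta = 0)        # pure cosine
#' s$delta                                           # 0
#' u <- seq(0, 1, by = 0.01)
#' plot(u, eval_wave_shape(s, u), type = "l")
#' @export
wave_shape <- function(alpha, beta, normalize = FALSE) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  D <- length(beta)
  if (D < 1L || length(alpha) != D + 1L)
    stop("need length(alpha) == length(beta) + 1 with at least one harmonic",
         call. = FALSE)
  if (!all(is.finite(alpha)) || !all(is.finite(beta)))
    stop("coefficients must be finite", call. = FALSE)
  a <- harmonic_magnitudes(alpha, beta)
  if (a[2L] <= 0)
    stop("degenerate shape: the fundamental harmonic has zero magnitude, ",
         "the dominance bound is undefined", call. = FALSE)
  energy <- shape_energy(alpha, beta)
  if (normalize) {
    sc <- 1 / sqrt(energy)
    alpha <- alpha * sc
    beta <- beta * sc
    a <- a * sc
    energy <- 1
  }
  delta <- max(a[-2L] / a[2L])
  structure(
    list(alpha = alpha, beta = beta, D = D, delta = delta, theta = 0,
         energy = energy),
    class = "wave_shape"
  )
}

# a_0 = |alpha_0|, a_l = sqrt(alpha_l^2 + beta_l^2)/2; returned as a
# vector indexed 0..D (R index 1..D+1).
harmonic_magnitudes <- function(alpha, beta) {
  c(abs(alpha[1L]), sqrt(alpha[-1L]^2 + beta^2) / 2)
}

shape_energy <- function(alpha, beta) {
  alpha[1L]^2 + sum(alpha[-1L]^2 + beta^2) / 2
}

#' Build a wave shape from harmonic magnitudes and phases
#'
#' Uses the polar parameterization of the Fourier coefficients,
#' \eqn{\alpha_\ell = 2 a_\ell \cos\theta_\ell},
#' \eqn{\beta_\ell = -2 a_\ell \sin\theta_\ell}, so that
#' \eqn{s(u) = \alpha_0 + 2\sum_\ell a_\ell \cos(2\pi\ell u + \theta_\ell)}.
#'
#' @param a numeric vector of harmonic magnitudes \eqn{a_1, \ldots, a_D}.
#' @param theta harmonic phases in radians (recycled if scalar).
#' @param a0 mean level \eqn{\alpha_0}.
#' @inheritParams wave_shape
#' @return A [wave_shape()] object.
#' @export
wave_shape_harmonics <- function(a, theta = 0, a0 = 0, normalize = FALSE) {
  theta <- rep_len(theta, length(a))
  wave_shape(alpha = c(a0, 2 * a * cos(theta)),
             beta = -2 * a * sin(theta),
             normalize = normalize)
}

#' Evaluate a wave-shape function
#'
#' @param shape a [wave_shape()] object.
#' @param u numeric vector of cycle positions (the template is 1-periodic,
#'   so `u` may be any real number).
#' @return Numeric vector `s(u)`.
#' @export
eval_wave_shape <- function(shape, u) {
  stopifnot(inherits(shape, "wave_shape"))
  D <- shape$D
  out <- rep(shape$alpha[1L], length(u))
  for (l in seq_len(D)) {
    w <- 2 * pi * l * u
    out <- out + shape$alpha[l + 1L] * cos(w) + shape$beta[l] * sin(w)
  }
  out
}

#' @export
print.wave_shape <- function(x, ...) {
  cat("Wave-shape function\n")
  cat(sprintf("  harmonics D = %d, dominance delta = %.3g, theta = %g\n",
              x$D, x$delta, x$theta))
  cat(sprintf("  energy = %.6g, mean level alpha0 = %.4g\n",
              x$energy, x$alpha[1L]))
  invisible(x)
}

#' @export
plot.wave_shape <- function(x, n_grid = 512L, ...) {
  u <- seq(0, 1, length.out = n_grid)
  plot(u, eval_wave_shape(x, u), type = "l",
       xlab = "cycle position u", ylab = "s(u)", ...)
  invisible(x)
}

# Harmonic magnitudes/phases of a shape, as complex z_l = a_l exp(i theta_l)
# for l = 1..D (beta = -2 a sin(theta) convention).
shape_harmonic_complex <- function(alpha, beta) {
  complex(real = alpha[-1L], imaginary = -beta) / 2
}
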