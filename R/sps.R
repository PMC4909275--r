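#' Functional design matrix for wave-shape regression
#'
#' Builds the `(2D + 1) x N` matrix of modulated harmonics
#' \deqn{c_0(k) = \tilde A(k),\quad
#'   c_\ell(k) = \tilde A(k)\cos(2\pi\ell\tilde\phi(k)),\quad
#'   d_\ell(k) = \tilde A(k)\sin(2\pi\ell\tilde\phi(k)),}
#' whose rows span the signals realizable by the adaptive non-harmonic
#' model at the estimated amplitude and phase.  Regressing the recorded
#' signal on these rows estimates the Fourier coefficients of the
#' wave-shape function.
#'
#' @param A amplitude trace, or a [reconstruct_component()] result (in
#'   which case `phi` is taken from it too).
#' @param phi phase trace in cycles.
#' @param D harmonic cutoff; 6 harmonics suffice for radial pulse
#'   waveforms.
#' @return An object of class `"sps_design"`: matrix `c` with named rows
#'   `a0, c1..cD, d1..dD`, and `D`.
#' @export
build_design <- function(A, phi = NULL, D = 6L) {
  if (inherits(A, "pulse_demod")) {
    phi <- A$phase
    A <- A$A
  }
  D <- as.integer(D)
  if (D < 1L) stop("need at least one harmonic", call. = FALSE)
  N <- length(A)
  if (length(phi) != N) stop("A and phi lengths differ", call. = FALSE)
  if (N <= 2L * (2L * D + 1L))
    stop("too few samples for 2D + 1 regression parameters", call. = FALSE)
  if (!all(is.finite(A)) || !all(is.finite(phi)))
    stop("non-finite values in the demodulation traces", call. = FALSE)
  C <- matrix(0, 2L * D + 1L, N)
  C[1L, ] <- A
  for (l in seq_len(D)) {
    w <- 2 * pi * l * phi
    C[1L + l, ] <- A * cos(w)
    C[1L + D + l, ] <- A * sin(w)
  }
  rownames(C) <- c("a0", paste0("c", seq_len(D)), paste0("d", seq_len(D)))
  structure(list(c = C, D = D), class = "sps_design")
}

#' Estimate the spectral pulse signature by least squares
#'
#' Solves the functional linear regression of the recorded samples on the
#' design rows, \eqn{\tilde\gamma = (Y c^T)(c c^T)^{-1}}, via a QR
#' factorization (mathematically identical to the normal-equation form
#' whenever \eqn{c c^T} is invertible).  The coefficient vector
#' \eqn{\tilde\gamma = (\tilde\alpha_0, \tilde\alpha_{1..D},
#' \tilde\beta_{1..D})} is the spectral pulse signature (SPS): the
#' estimated Fourier coefficients of the wave-shape function, phases
#' included.
#'
#' @param y numeric vector of recorded samples (same length as the design
#'   columns), or a [pulse_signal()].
#' @param design an [build_design()] result.
#' @return An object of class `"sps"`: `gamma` (named), `D`, `se`
#'   (coefficient standard errors from the OLS covariance), `sigma`
#'   (residual standard deviation), `condition` (condition number of
#'   \eqn{c c^T}) and `fitted`/`residuals`.
#' @export
fit_sps <- function(y, design) {
  stopifnot(inherits(design, "sps_design"))
  if (inherits(y, "pulse_signal")) y <- y$samples
  C <- design$c
  if (length(y) != ncol(C))
    stop("signal and design lengths differ", call. = FALSE)
  X <- t(C)
  d <- svd(X, nu = 0, nv = 0)$d
  cond <- if (min(d) == 0) Inf else (max(d) / min(d))^2  # cond of c c^T
  if (!is.finite(cond) || cond > 1e12)
    stop("ill-conditioned design (degenerate phase or amplitude)",
         call. = FALSE)
  if (cond > 1e8)
    warning("design condition number above 1e8; SPS estimates may be unstable")
  fit <- lm.fit(X, y)
  gamma <- fit$coefficients
  p <- length(gamma)
  n <- length(y)
  sigma2 <- sum(fit$residuals^2) / max(1L, n - p)
  XtXinv <- chol2inv(qr.R(fit$qr))
  structure(list(gamma = gamma, D = design$D,
                 se = sqrt(sigma2 * diag(XtXinv)), sigma = sqrt(sigma2),
                 condition = cond, fitted = fit$fitted.values,
                 residuals = fit$residuals),
            class = "sps")
}

#' @export
print.sps <- function(x, digits = 4, ...) {
  cat(sprintf("Spectral pulse signature (D = %d)\n", x$D))
  print(round(x$gamma, digits))
  cat(sprintf("residual sd %.4g, design condition %.3g\n",
              x$sigma, x$condition))
  invisible(x)
}

#' @export
coef.sps <- function(object, ...) object$gamma

#' Reconstruct the oscillatory signal from an SPS
#'
#' Evaluates \eqn{\tilde f = \tilde\gamma^T c}, the model-implied clean
#' signal at the demodulated amplitude and phase.
#'
#' @param sps an [fit_sps()] result or bare coefficient vector.
#' @param design the matching [build_design()] result.
#' @return Numeric vector of length `N`.
#' @export
reconstruct_signal <- function(sps, design) {
  stopifnot(inherits(design, "sps_design"))
  gamma <- if (inherits(sps, "sps")) sps$gamma else as.numeric(sps)
  if (length(gamma) != nrow(design$c))
    stop("SPS dimension does not match the design", call. = FALSE)
  as.numeric(gamma %*% design$c)
}

#' Harmonic power of a spectral pulse signature
#'
#' The estimated power of the \eqn{\ell}-th harmonic of the wave-shape
#' function, \eqn{p_\ell = (\tilde\alpha_\ell^2 + \tilde\beta_\ell^2)/4 =
#' a_\ell^2}, for \eqn{\ell = 1..D}.  This is the quantity classical
#' pulse spectral analysis reports; unlike the SPS it discards the
#' harmonic phases.
#'
#' @param sps an [fit_sps()] result or coefficient vector
#'   \eqn{(\alpha_0, \alpha_{1..D}, \beta_{1..D})}.
#' @return Numeric vector of length `D`.
#' @export
harmonic_power <- function(sps) {
  g <- if (inherits(sps, "sps")) sps$gamma else as.numeric(sps)
  D <- (length(g) - 1L) %/% 2L
  (g[2L:(D + 1L)]^2 + g[(D + 2L):(2L * D + 1L)]^2) / 4
}

#' Sample the wave-shape function encoded by an SPS
#'
#' @inheritParams harmonic_power
#' @param n_grid number of points on the uniform unit-period grid.
#' @return Numeric vector `s(u)` at `u = 0, 1/n_grid, ...`.
#' @export
sps_to_shape <- function(sps, n_grid = 256L) {
  g <- if (inherits(sps, "sps")) sps$gamma else as.numeric(sps)
  D <- (length(g) - 1L) %/% 2L
  if (n_grid < 2L * D + 1L)
    stop("n_grid too coarse for the harmonic content", call. = FALSE)
  u <- (seq_len(n_grid) - 1L) / n_grid
  out <- rep(g[1L], n_grid)
  for (l in seq_len(D)) {
    w <- 2 * pi * l * u
    out <- out + g[1L + l] * cos(w) + g[1L + D + l] * sin(w)
  }
  out
}

#' Standardize an SPS to its canonical gauge
#'
#' The adaptive non-harmonic model leaves two gauges free: the split of
#' scale between amplitude and template (fixed by unit template energy)
#' and the cycle origin (fixed by zeroing the first-harmonic phase).
#' Demodulation-based estimates land in an arbitrary gauge — the
#' reconstructed amplitude absorbs the fundamental's magnitude and the
#' unwrapped phase absorbs its phase offset — so signatures are
#' standardized before records are compared.
#'
#' @inheritParams harmonic_power
#' @param unit_energy rescale to unit template energy.
#' @param zero_first_phase rotate the cycle origin so
#'   \eqn{\theta_1 = 0} (fundamental a pure cosine).
#' @return A named coefficient vector in the same layout as the input.
#' @export
sps_standardize <- function(sps, unit_energy = TRUE,
                            zero_first_phase = TRUE) {
  g <- if (inherits(sps, "sps")) sps$gamma else as.numeric(sps)
  D <- (length(g) - 1L) %/% 2L
  alpha <- g[1L:(D + 1L)]
  beta <- g[(D + 2L):(2L * D + 1L)]
  z <- shape_harmonic_complex(alpha, beta)     # a_l exp(i theta_l)
  a0 <- alpha[1L]
  if (zero_first_phase) {
    if (Mod(z[1L]) == 0)
      stop("cannot zero the first-harmonic phase of a signature with no ",
           "fundamental", call. = FALSE)
    rot <- -Arg(z[1L])                          # theta_l -> theta_l - l theta_1
    z <- z * exp(1i * rot * seq_len(D))
  }
  alpha <- c(a0, 2 * Re(z))
  beta <- -2 * Im(z)
  if (unit_energy) {
    e <- shape_energy(alpha, beta)
    if (e == 0) stop("zero-energy signature", call. = FALSE)
    alpha <- alpha / sqrt(e)
    beta <- beta / sqrt(e)
  }
  out <- c(alpha, beta)
  names(out) <- c("a0", paste0("c", seq_len(D)), paste0("d", seq_len(D)))
  out
}
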