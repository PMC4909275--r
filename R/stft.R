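#' Gaussian analysis window
#'
#' Samples the Gaussian window
#' \eqn{h(t) = (2\pi\sigma)^{-1/2} e^{-t^2/\sigma^2}}
#' and its derivative \eqn{h'(t)} on `[-half_width, half_width]` at `1/fs`
#' spacing.  The normalization follows the convention used throughout the
#' analysis; any fixed rescaling of the window cancels in the
#' \eqn{h(0)^{-1}} factor of the band reconstruction.
#'
#' @param sigma kernel bandwidth in seconds.  The default 0.5 s matches a
#'   window long enough to cover roughly one cardiac cycle while keeping
#'   beat-to-beat dynamics visible.
#' @param half_width truncation half-width in seconds; the default
#'   `4 * sigma` retains all but a negligible fraction of the window mass.
#' @param fs sampling rate, Hz.
#' @return A list of class `"gaussian_window"` with `h`, `dh` (samples of
#'   \eqn{h} and \eqn{h'}), `t` (their times), `h0` (\eqn{h(0)}), `sigma`,
#'   `half_width` and `fs`.
#' @examples
#' w <- gaussian_window(0.5, fs = 100)
#' w$h0                # (2 pi 0.5)^(-1/2) = 1/sqrt(pi)
#' @export
gaussian_window <- function(sigma = 0.5, half_width = 4 * sigma, fs) {
  stopifnot_scalar(sigma, "sigma")
  stopifnot_scalar(half_width, "half_width")
  stopifnot_scalar(fs, "fs")
  if (half_width < 2 / fs)
    stop("window half-width shorter than two samples", call. = FALSE)
  m <- floor(half_width * fs)
  t <- (-m:m) / fs
  h <- (2 * pi * sigma)^(-1 / 2) * exp(-t^2 / sigma^2)
  dh <- h * (-2 * t / sigma^2)
  structure(list(h = h, dh = dh, t = t, h0 = (2 * pi * sigma)^(-1 / 2),
                 sigma = sigma, half_width = half_width, fs = fs),
            class = "gaussian_window")
}

#' Short-time Fourier transform with a Gaussian window
#'
#' Computes the modulated sliding-window transform
#' \deqn{V(t, \eta) = \int f(t+u)\, h(u)\, e^{-i 2\pi \eta u}\, du}
#' discretized on the signal grid (one frame per `hop` samples, boundary
#' frames zero-padded), evaluated by FFT on a frequency grid
#' `0, df, ..., freq_max` with `df = fs / n_fft`.  The transform is also
#' computed with the differentiated window \eqn{h'}, which the
#' reassignment operator of the synchrosqueezing transform requires.
#'
#' @param x a [pulse_signal()] or numeric vector.
#' @param fs sampling rate, required when `x` is a bare vector.
#' @param window a [gaussian_window()]; built from `sigma` when missing.
#' @param sigma window bandwidth in seconds (used when `window` missing).
#' @param freq_max top of the frequency grid, Hz; must not exceed `fs/2`.
#'   The default 10 Hz holds the first six harmonics of any plausible
#'   resting heart rate.
#' @param df frequency grid spacing, Hz.  The grid oversamples the native
#'   resolution of a short record; the default 0.02 Hz sharpens ridge
#'   reading without inventing resolution.
#' @param hop frame step in samples; 1 keeps an estimate at every sample,
#'   as the downstream demodulation and regression require.
#' @return An object of class `"pulse_stft"`: complex matrices `values`
#'   and `dvalues` (frames x frequency bins), `times`, `freqs`, `dt`,
#'   `df`, `window`.
#' @export
stft <- function(x, fs = NULL, window = NULL, sigma = 0.5,
                 freq_max = 10, df = 0.02, hop = 1L) {
  sig <- as_pulse_signal(x, fs)
  fs <- sig$fs
  if (freq_max > fs / 2)
    stop("freq_max exceeds the Nyquist frequency", call. = FALSE)
  if (is.null(window)) window <- gaussian_window(sigma, fs = fs)
  n <- length(sig$samples)
  m <- (length(window$h) - 1L) / 2L
  if (length(window$h) > n)
    stop("window longer than the signal", call. = FALSE)
  n_fft <- max(round(fs / df), 2L * m + 1L)
  df <- fs / n_fft
  n_bins <- floor(freq_max / df) + 1L
  frames <- seq(1L, n, by = hop)
  xp <- c(rep(0, m), sig$samples, rep(0, m))

  vals <- frame_fft(xp, frames, m, window$h, n_fft, n_bins)
  dvals <- frame_fft(xp, frames, m, window$dh, n_fft, n_bins)
  dt <- 1 / fs
  structure(list(values = vals * dt, dvalues = dvals * dt,
                 times = sig$t0 + (frames - 1L) * dt,
                 freqs = (seq_len(n_bins) - 1L) * df,
                 dt = dt, df = df, hop = hop, window = window),
            class = "pulse_stft")
}

# FFT over frames in blocks.  The windowed segment occupies lags
# -m..m; lag j goes to FFT position (j mod n_fft) so that bin k holds
# sum_j g[j] exp(-i 2 pi k j / n_fft).
frame_fft <- function(xp, frames, m, h, n_fft, n_bins, block = 128L) {
  n_frames <- length(frames)
  out <- matrix(0+0i, n_frames, n_bins)
  pos <- c((n_fft - m + 1L):n_fft, 1L:(m + 1L)) # lags -m..m, wrapped
  for (start in seq(1L, n_frames, by = block)) {
    idx <- start:min(start + block - 1L, n_frames)
    buf <- matrix(0, n_fft, length(idx))
    for (j in seq_along(idx)) {
      k <- frames[idx[j]]
      buf[pos, j] <- xp[k:(k + 2L * m)] * h
    }
    out[idx, ] <- t(stats::mvfft(buf)[seq_len(n_bins), , drop = FALSE])
  }
  out
}

as_pulse_signal <- function(x, fs = NULL) {
  if (inherits(x, "pulse_signal")) return(x)
  if (is.null(fs)) stop("fs is required for a bare sample vector", call. = FALSE)
  pulse_signal(x, fs = fs)
}

#' Reassignment frequency operator
#'
#' For every time-frequency cell with \eqn{|V(t,\eta)|} at or above
#' `threshold` times the frame maximum, computes the reassignment
#' frequency
#' \deqn{\omega(t,\eta) = \eta - \mathrm{Im}\!\left(
#'   \frac{V^{(h')}(t,\eta)}{V^{(h)}(t,\eta)}\right) / (2\pi),}
#' the demodulated local frequency that the synchrosqueezing transform
#' reallocates energy to.  Cells below the threshold get `-Inf` and are
#' excluded from squeezing.
#'
#' @param stft a [stft()] result (carries both window transforms).
#' @param threshold relative magnitude threshold guarding the division.
#' @return Real matrix of reassignment frequencies (Hz), `-Inf` where
#'   undefined.
#' @export
reassignment_frequency <- function(stft, threshold = 1e-4) {
  stopifnot(inherits(stft, "pulse_stft"))
  mag <- Mod(stft$values)
  frame_max <- apply(mag, 1L, max)
  keep <- mag >= threshold * frame_max & frame_max > 0
  omega <- matrix(-Inf, nrow(mag), ncol(mag))
  eta <- matrix(stft$freqs, nrow(mag), ncol(mag), byrow = TRUE)
  omega[keep] <- eta[keep] -
    Im(stft$dvalues[keep] / stft$values[keep]) / (2 * pi)
  omega
}

#' Synchrosqueezing transform
#'
#' Reallocates each retained STFT coefficient (complex-valued, phase
#' preserved) along the frequency axis into the output bin containing its
#' reassignment frequency, scaled by the input bin width.  The result is
#' a sharpened time-frequency representation that still supports
#' band-limited reconstruction of the oscillatory component.
#'
#' @param stft a [stft()] result.
#' @param omega reassignment frequencies from [reassignment_frequency()];
#'   computed internally when `NULL`.
#' @param out_freqs uniform output frequency grid; defaults to the STFT
#'   grid.
#' @param threshold relative magnitude threshold, as in
#'   [reassignment_frequency()].
#' @return An object of class `"pulse_sst"`: complex matrix `values`
#'   (frames x output bins), `times`, `freqs`, `df`, `omega`, and the
#'   originating window.
#' @export
synchrosqueeze <- function(stft, omega = NULL, out_freqs = NULL,
                           threshold = 1e-4) {
  stopifnot(inherits(stft, "pulse_stft"))
  if (is.null(omega)) omega <- reassignment_frequency(stft, threshold)
  if (is.null(out_freqs)) out_freqs <- stft$freqs
  n_out <- length(out_freqs)
  if (n_out < 2L) stop("output grid needs at least two bins", call. = FALSE)
  dfo <- diff(out_freqs)
  if (max(abs(dfo - dfo[1L])) > 1e-9 * dfo[1L])
    stop("output frequency grid must be uniform", call. = FALSE)
  dfo <- dfo[1L]
  n_frames <- nrow(stft$values)

  bin <- round((omega - out_freqs[1L]) / dfo) + 1L
  ok <- is.finite(omega) & bin >= 1L & bin <= n_out
  # column-major linear index of [frame, bin] in the output matrix
  lin <- (bin[ok] - 1L) * n_frames + row(bin)[ok]
  # reallocated coefficients accumulate as a density on the output grid:
  # each input cell contributes V * d_eta, spread over one output bin
  v <- stft$values[ok] * (stft$df / dfo)
  re <- rowsum(Re(v), lin)
  im <- rowsum(Im(v), lin)
  vals <- matrix(0+0i, n_frames, n_out)
  vals[as.integer(rownames(re))] <-
    complex(real = re[, 1L], imaginary = im[, 1L])
  structure(list(values = vals, times = stft$times, freqs = out_freqs,
                 df = dfo, dt = stft$dt, omega = omega,
                 window = stft$window),
            class = "pulse_sst")
}

#' @export
print.pulse_stft <- function(x, ...) {
  cat(sprintf("STFT: %d frames x %d bins, dt = %g s, df = %g Hz, sigma = %g s\n",
              nrow(x$values), ncol(x$values), x$dt * x$hop, x$df,
              x$window$sigma))
  invisible(x)
}

#' @export
print.pulse_sst <- function(x, ...) {
  cat(sprintf("SST: %d frames x %d bins, df = %g Hz\n",
              nrow(x$values), ncol(x$values), x$df))
  invisible(x)
}

#' @export
plot.pulse_sst <- function(x, log_mag = TRUE, ...) {
  z <- Mod(x$values)
  if (log_mag) z <- log10(z + 1e-12)
  image(x$times, x$freqs, z, col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "time (s)", ylab = "frequency (Hz)", ...)
  invisible(x)
}
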