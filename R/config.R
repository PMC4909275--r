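#' Analysis configuration
#'
#' Collects every tunable of the analysis chain with its default.  The
#' defaults encode the study conditions the estimator was designed for:
#' a Gaussian window of bandwidth 0.5 s, six wave-shape harmonics,
#' 1000 bootstrap replicas for the AUC confidence interval, 200 repeats
#' of leave-one-out cross-validation and a 0.01 significance level for
#' the functional ANOVA.
#'
#' @param sigma Gaussian window bandwidth, seconds.
#' @param half_width window truncation half-width, seconds; also the
#'   edge-trim span excluded from the wave-shape regression.
#' @param hop STFT frame step in samples.
#' @param freq_max top of the frequency grid, Hz.
#' @param df frequency bin width, Hz.
#' @param threshold relative STFT magnitude threshold for reassignment.
#' @param search_band ridge search band, Hz (length 2).
#' @param lambda ridge smoothness penalty.
#' @param band_hz reconstruction half-band around the ridge, Hz.
#' @param smooth_hz low-pass cutoff for the demodulated amplitude and
#'   phase-increment traces, Hz (see [reconstruct_component()]); 0
#'   disables smoothing.
#' @param D harmonic cutoff of the wave-shape function.
#' @param n_components PLS components for the global pulse signature.
#' @param n_perm label permutations for the functional ANOVA.
#' @param n_boot bootstrap replicas for the AUC confidence interval.
#' @param n_repeats leave-one-out cross-validation repeats.
#' @param alpha significance level for the functional ANOVA.
#' @param seed default master seed for stochastic operations.
#' @return An object of class `"pulse_config"` (a validated named list).
#' @export
pulse_config <- function(sigma = 0.5, half_width = 4 * sigma, hop = 1L,
                         freq_max = 10, df = 0.02, threshold = 1e-4,
                         search_band = c(0.5, 3), lambda = 1,
                         band_hz = 0.25, smooth_hz = 0.5, D = 6L,
                         n_components = 2L,
                         n_perm = 999L, n_boot = 1000L, n_repeats = 200L,
                         alpha = 0.01, seed = 1L) {
  cfg <- list(sigma = sigma, half_width = half_width, hop = as.integer(hop),
              freq_max = freq_max, df = df, threshold = threshold,
              search_band = as.numeric(search_band), lambda = lambda,
              band_hz = band_hz, smooth_hz = smooth_hz, D = as.integer(D),
              n_components = as.integer(n_components),
              n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
              n_repeats = as.integer(n_repeats), alpha = alpha,
              seed = as.integer(seed))
  for (nm in c("sigma", "half_width", "freq_max", "df", "threshold",
               "lambda", "band_hz", "alpha"))
    stopifnot_scalar(cfg[[nm]], nm)
  if (!is.numeric(cfg$smooth_hz) || cfg$smooth_hz < 0)
    stop("'smooth_hz' must be a non-negative number", call. = FALSE)
  if (length(cfg$search_band) != 2L || diff(cfg$search_band) <= 0)
    stop("search_band must be an increasing (low, high) pair", call. = FALSE)
  for (nm in c("hop", "D", "n_components", "n_perm", "n_boot", "n_repeats"))
    if (cfg[[nm]] < 1L) stop(sprintf("'%s' must be >= 1", nm), call. = FALSE)
  if (cfg$alpha >= 1) stop("alpha must be below 1", call. = FALSE)
  class(cfg) <- "pulse_config"
  cfg
}

#' @export
print.pulse_config <- function(x, ...) {
  cat("Pulse analysis configuration\n")
  cat(sprintf("  window: sigma %g s, half-width %g s, hop %d\n",
              x$sigma, x$half_width, x$hop))
  cat(sprintf("  frequency grid: 0-%g Hz at %g Hz\n", x$freq_max, x$df))
  cat(sprintf(
    "  ridge: band %g-%g Hz, lambda %g; reconstruction +/- %g Hz, trace smoothing %g Hz\n",
    x$search_band[1L], x$search_band[2L], x$lambda, x$band_hz, x$smooth_hz))
  cat(sprintf("  shape: D = %d harmonics\n", x$D))
  cat(sprintf("  cohort: %d PLS components, %d permutations, %d bootstrap, %d LOOCV repeats, alpha %g\n",
              x$n_components, x$n_perm, x$n_boot, x$n_repeats, x$alpha))
  invisible(x)
}

#' Read and write analysis configurations
#'
#' Configurations serialize to YAML with full round-trip fidelity.
#'
#' @param config a [pulse_config()] object.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a validated [pulse_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pulse_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pulse_config, raw)
}
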