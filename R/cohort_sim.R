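#' Built-in wave-shape templates
#'
#' Phenomenological radial-pulse templates used as cohort defaults.  Both
#' have six harmonics with decaying magnitudes and progressive harmonic
#' phases (which produce the steep upstroke / slow decay asymmetry of an
#' arterial pressure wave); the "case" template carries relatively more
#' energy in harmonics 2-4, the pattern of a stiffer, altered waveform.
#' Both are unit-energy with the fundamental phase zero, i.e. already in
#' the canonical gauge of [sps_standardize()].
#'
#' @param which `"control"` or `"case"`.
#' @return A [wave_shape()] with `D = 6`.
#' @export
pulse_template <- function(which = c("control", "case")) {
  which <- match.arg(which)
  a <- switch(which,
    control = c(1, 0.55, 0.32, 0.18, 0.09, 0.045),
    case    = c(1, 0.72, 0.47, 0.30, 0.15, 0.075))
  theta <- switch(which,
    control = c(0, 0.7, 1.4, 2.1, 2.8, 3.5),
    case    = c(0, 0.9, 1.8, 2.7, 3.6, 4.5))
  wave_shape_harmonics(a = a, theta = theta, a0 = 0.35, normalize = TRUE)
}

#' Simulate a labeled cohort of pulse records
#'
#' Generates independent synthetic pulse records for a control and a case
#' group.  Each record draws its own wave shape around the group template
#' (Gaussian jitter of the Fourier coefficients with standard deviation
#' `coef_sd`, re-normalized to unit energy), its own heart-rate
#' variability and amplitude-modulation realization, and its own additive
#' ARMA noise with Student-t innovations at `snr_db`.  Defaults emulate
#' the recording conditions of resting radial tonometry: 10-s records at
#' 100 Hz, instantaneous frequency near 1-1.2 Hz with ~±8% sinusoidal
#' modulation, ~±8% slow amplitude modulation, and 0 dB ARMA(1,1)/t3
#' noise.
#'
#' @param n_control,n_case records per group.
#' @param control_shape,case_shape group templates ([wave_shape()]).
#' @param coef_sd within-group standard deviation of each Fourier
#'   coefficient around the template.
#' @param mean_if_range per-record mean heart rate drawn uniformly from
#'   this range (Hz).
#' @param if_depth,if_freq sinusoidal IF modulation: depth as a fraction
#'   of the record's mean IF, modulation frequency in Hz.
#' @param am_depth,am_freq sinusoidal amplitude modulation depth (about
#'   1) and frequency (Hz).
#' @param snr_db signal-to-noise ratio of the added ARMA noise, dB; `Inf`
#'   disables noise.
#' @param noise arguments passed to [arma_t_noise()] (list with `ar`,
#'   `ma`, `dof`).
#' @param fs sampling rate, Hz.
#' @param duration record length, seconds.
#' @param seed master seed; the cohort is fully reproducible from it.
#' @return An object of class `"pulse_cohort"`: `records` (list of
#'   [pulse_signal()]), `labels` (0 control / 1 case), `truth` (list of
#'   per-record generator parameters: shape, imt), and the call
#'   arguments.
#' @examples
#' co <- simulate_cohort(3, 3, duration = 10, seed = 7)
#' table(co$labels)
#' @export
simulate_cohort <- function(n_control, n_case,
                            control_shape = pulse_template("control"),
                            case_shape = pulse_template("case"),
                            coef_sd = 0.04,
                            mean_if_range = c(1.0, 1.2),
                            if_depth = 0.08, if_freq = 0.1,
                            am_depth = 0.08, am_freq = 0.15,
                            snr_db = 0,
                            noise = list(ar = 0.5, ma = -0.3, dof = 3),
                            fs = 100, duration = 10, seed = 1L) {
  stopifnot(n_control >= 1L, n_case >= 1L,
            inherits(control_shape, "wave_shape"),
            inherits(case_shape, "wave_shape"))
  n <- n_control + n_case
  labels <- rep(c(0L, 1L), c(n_control, n_case))
  seeds <- derive_seeds(seed, n)
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- if (labels[i] == 0L) control_shape else case_shape
    rec <- with_seed(seeds[i], {
      shape <- jitter_shape(tmpl, coef_sd)
      mif <- runif(1, mean_if_range[1L], mean_if_range[2L])
      params <- hrv_phase(
        fs, duration, mean_if = mif,
        if_modulation = list(type = "sine", depth = if_depth * mif,
                             freq = if_freq, phase = NULL),
        am_modulation = list(type = "sine", depth = am_depth,
                             freq = am_freq, phase = NULL),
        phi0 = runif(1))
      clean <- synthesize_imt(shape, params)
      out <- if (is.finite(snr_db)) {
        eps <- arma_t_noise(length(clean$samples), ar = noise$ar,
                            ma = noise$ma, dof = noise$dof)
        add_noise_at_snr(clean, eps, snr_db)
      } else clean
      list(signal = out, shape = shape, imt = params)
    })
    records[[i]] <- rec$signal
    truth[[i]] <- list(shape = rec$shape, imt = rec$imt, seed = seeds[i])
  }
  structure(list(records = records, labels = labels, truth = truth,
                 fs = fs, duration = duration, snr_db = snr_db,
                 coef_sd = coef_sd, seed = as.integer(seed)),
            class = "pulse_cohort")
}

# Gaussian jitter on the Fourier coefficients, re-normalized to unit
# energy.  With sd = 0 the template is returned unchanged.
jitter_shape <- function(shape, sd) {
  if (sd == 0) return(shape)
  wave_shape(alpha = shape$alpha + rnorm(shape$D + 1L, sd = sd),
             beta = shape$beta + rnorm(shape$D, sd = sd),
             normalize = TRUE)
}

#' @export
print.pulse_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic pulse cohort: %d control + %d case records (%g s at %g Hz, SNR %g dB)\n",
    sum(x$labels == 0L), sum(x$labels == 1L), x$duration, x$fs, x$snr_db))
  invisible(x)
}

#' Spectral pulse signatures of a cohort
#'
#' Runs [pulse_fit()] on every record and stacks the standardized
#' signatures into the feature matrix used by the cohort statistics.
#'
#' @param cohort a [simulate_cohort()] result, or a list of
#'   [pulse_signal()] records plus `labels`.
#' @param config analysis settings, see [pulse_config()].
#' @param labels 0/1 group labels when `cohort` is a bare list.
#' @param oracle use the generator's ground-truth demodulation instead of
#'   the time-frequency chain (synthetic cohorts only).
#' @return A list of class `"cohort_sps"`: matrix `X` (records x
#'   `2D + 1`), `labels`, and the per-record fits' heart-rate summaries.
#' @export
cohort_sps <- function(cohort, config = pulse_config(), labels = NULL,
                       oracle = FALSE) {
  if (inherits(cohort, "pulse_cohort")) {
    records <- cohort$records
    labels <- cohort$labels
    truth <- cohort$truth
  } else {
    records <- cohort
    truth <- NULL
    if (is.null(labels) || length(labels) != length(records))
      stop("labels are required (one per record)", call. = FALSE)
  }
  if (oracle && is.null(truth))
    stop("oracle demodulation needs generator ground truth", call. = FALSE)
  fits <- lapply(seq_along(records), function(i) {
    dm <- if (oracle)
      list(A = truth[[i]]$imt$A, phi = truth[[i]]$imt$phi) else NULL
    pulse_fit(records[[i]], config = config, demod = dm)
  })
  X <- do.call(rbind, lapply(fits, coef))
  hr <- if (oracle) NULL else
    t(vapply(fits, function(f) c(mean = mean(f$ridge$if_hz),
                                 sd = sd(f$ridge$if_hz)), numeric(2)))
  structure(list(X = X, labels = as.integer(labels), heart_rate = hr,
                 D = config$D), class = "cohort_sps")
}
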