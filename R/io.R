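#' Read a pulse signal from delimited text
#'
#' Accepts one-column files (amplitude only; `fs` required) and
#' two-column files (time in seconds, amplitude), with an optional header
#' line.  Timestamps must be uniform to within a relative jitter of
#' 1e-6; rows with non-finite values are dropped with a warning.
#'
#' @param path file path.
#' @param fs sampling rate override, Hz; required for one-column files,
#'   and checked against the timestamps otherwise.
#' @param sep field separator, passed to [utils::read.table()].
#' @return A [pulse_signal()].
#' @export
read_signal <- function(path, fs = NULL, sep = "") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty signal file: ", path, call. = FALSE)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), sprintf("[%s,;\t ]+",
                                               sep))[[1L]][1L])))
  tab <- read.table(path, header = has_header, sep = sep,
                    comment.char = "#")
  if (nrow(tab) == 0L) stop("empty signal file: ", path, call. = FALSE)
  if (ncol(tab) == 1L) {
    if (is.null(fs))
      stop("one-column file: a sampling rate is required", call. = FALSE)
    y <- as.numeric(tab[[1L]])
    bad <- !is.finite(y)
    if (any(bad)) {
      warning(sprintf("dropped %d non-finite row(s)", sum(bad)))
      y <- y[!bad]
    }
    return(pulse_signal(y, fs = fs))
  }
  t <- as.numeric(tab[[1L]])
  y <- as.numeric(tab[[2L]])
  bad <- !is.finite(t) | !is.finite(y)
  if (any(bad)) {
    warning(sprintf("dropped %d non-finite row(s)", sum(bad)))
    t <- t[!bad]; y <- y[!bad]
  }
  if (length(y) < 2L) stop("fewer than two usable rows", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - stats::median(dt))) >
        1e-6 * stats::median(dt))
    stop("non-uniform timestamps (relative jitter above 1e-6)",
         call. = FALSE)
  fs_file <- 1 / stats::median(dt)
  if (!is.null(fs) && abs(fs - fs_file) > 1e-6 * fs_file)
    stop(sprintf("fs override (%g) contradicts timestamps (%g)",
                 fs, fs_file), call. = FALSE)
  pulse_signal(y, fs = fs_file, t0 = t[1L])
}

#' Write a pulse signal to delimited text
#'
#' Writes a two-column (time, amplitude) table.  Optional metadata (e.g.
#' the sampling rate, generator seed and ground-truth parameters of a
#' synthetic fixture) is written to a YAML sidecar `<path>.meta.yaml`.
#'
#' @param x a [pulse_signal()].
#' @param path output path.
#' @param meta optional named list written to the sidecar; the sampling
#'   rate is always included.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, meta = NULL) {
  stopifnot(inherits(x, "pulse_signal"))
  tab <- data.frame(time_s = signal_times(x), amplitude = x$samples)
  write.table(format(tab, digits = 15, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta)) {
    meta <- c(list(fs = x$fs), meta)
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15L)
  }
  invisible(path)
}

#' Write a cohort manifest and its signal files
#'
#' Persists every record of a cohort as a delimited signal file plus a
#' manifest table (path, label, subject id) — the on-disk interchange
#' format for cohort-level analysis.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pulse_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort$records)
  paths <- file.path(dir, sprintf("record_%03d.tsv", seq_len(n)))
  for (i in seq_len(n))
    write_signal(cohort$records[[i]], paths[i],
                 meta = list(seed = cohort$truth[[i]]$seed,
                             label = cohort$labels[i]))
  manifest <- data.frame(path = basename(paths), label = cohort$labels,
                         subject_id = sprintf("S%03d", seq_len(n)))
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort manifest
#'
#' @param path manifest path, as written by [write_cohort()]; signal
#'   files are resolved relative to its directory.
#' @return A list with `records` (list of [pulse_signal()]) and `labels`,
#'   usable with [cohort_sps()].
#' @export
read_cohort <- function(path) {
  manifest <- read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  dir <- dirname(path)
  records <- lapply(file.path(dir, manifest$path), read_signal)
  list(records = records, labels = as.integer(manifest$label))
}
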