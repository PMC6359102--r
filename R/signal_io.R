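#' Signal records and window specifications
#'
#' A `signal_record` holds one peripheral physiological channel: blood volume
#' pulse (BVP, photoplethysmography, typically 128 Hz) or galvanic skin
#' response (GSR, skin conductance in microsiemens, typically 4 Hz).
#'
#' @param samples numeric vector of samples, in channel units.
#' @param sampling_rate sampling rate in samples/second (positive).
#' @param channel `"BVP"` or `"GSR"`.
#' @param start_time recording start, seconds since epoch.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, sampling_rate, channel = c("BVP", "GSR"),
                          start_time = 0) {
  channel <- match.arg(channel)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  samples <- as.numeric(samples)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel = channel, start_time = as.numeric(start_time)),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("signal_record: %s, %g Hz, %d samples (%.2f s), start %.3f\n",
              x$channel, x$sampling_rate, length(x$samples),
              length(x$samples) / x$sampling_rate, x$start_time))
  invisible(x)
}

#' Duration of a signal record in seconds
#' @param x a `signal_record`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$sampling_rate

#' Read a single-channel signal CSV (E4-style dialect)
#'
#' File layout: line 1 is the UTC start time in seconds (real), line 2 the
#' sampling rate in Hz (real), and every following line one sample. One file
#' per channel, conventionally named `<session>_<CHANNEL>.csv`.
#'
#' @param path path to the CSV file.
#' @param channel `"BVP"` or `"GSR"`.
#' @return A [signal_record()].
#' @export
read_signal_csv <- function(path, channel = c("BVP", "GSR")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop("malformed signal file (need start-time and sample-rate header ",
         "lines): ", path)
  }
  start_time <- suppressWarnings(as.numeric(lines[1]))
  if (is.na(start_time)) {
    stop("malformed header line 1 (start time) in ", path, ": ", lines[1])
  }
  fs <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(fs) || fs <= 0) {
    stop("malformed header line 2 (sample rate) in ", path, ": ", lines[2])
  }
  data_lines <- lines[-(1:2)]
  samples <- suppressWarnings(as.numeric(data_lines))
  bad <- which(is.na(samples) & !is.na(data_lines))
  if (length(bad) > 0) {
    stop("non-numeric sample at line ", bad[1] + 2, " in ", path, ": ",
         data_lines[bad[1]])
  }
  signal_record(samples, fs, channel, start_time)
}

#' Write a single-channel signal CSV (E4-style dialect)
#'
#' Inverse of [read_signal_csv()]; samples are written at 9 significant
#' digits so that read-after-write reproduces them to text round-trip
#' precision.
#'
#' @param record a `signal_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  lines <- c(format(record$start_time, digits = 9, scientific = FALSE),
             format(record$sampling_rate, digits = 9, scientific = FALSE),
             format(record$samples, digits = 9, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Sliding-window specification
#'
#' @param window_length window length in seconds.
#' @param hop hop (stride) between window starts in seconds; must satisfy
#'   `0 < hop <= window_length`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_length = 3, hop = 1) {
  if (window_length <= 0) stop("window_length must be positive")
  if (hop <= 0 || hop > window_length) {
    stop("hop must satisfy 0 < hop <= window_length")
  }
  structure(list(window_length = window_length, hop = hop),
            class = "window_spec")
}

#' Cut aligned sliding windows across channels
#'
#' Windows are defined in seconds on a shared clock starting at the common
#' start time; each channel contributes the samples whose timestamps fall in
#' the half-open interval `[start, end)` on that channel's own sample grid,
#' which keeps a 128 Hz and a 4 Hz channel aligned without cumulative
#' off-by-one drift. Windows extending past the end of the shortest channel
#' are not emitted. A window's label is the label-track value at the window
#' end time (the window summarizes the last `window_length` seconds of
#' signal leading up to its end).
#'
#' @param signals list of `signal_record`s (typically one BVP, one GSR).
#' @param spec a [window_spec()].
#' @param label_fun optional function of time (seconds from recording start)
#'   returning the continuous label in `[0, 1]`; evaluated at each window's
#'   end time. `NULL` leaves windows unlabeled.
#' @param subject_id opaque subject identifier attached to every window.
#' @return A list of `windowed_segment` objects, each with elements
#'   `channels` (named list of numeric vectors), `start`, `end`, `label`
#'   (or `NA`), `subject_id`, and per-channel sampling rates `fs`.
#' @export
segment_windows <- function(signals, spec, label_fun = NULL,
                            subject_id = "s1") {
  stopifnot(inherits(spec, "window_spec"))
  if (inherits(signals, "signal_record")) signals <- list(signals)
  stopifnot(length(signals) >= 1)
  for (s in signals) stopifnot(inherits(s, "signal_record"))
  names(signals) <- vapply(signals, function(s) s$channel, character(1))

  duration <- min(vapply(signals, signal_duration, numeric(1)))
  if (duration < spec$window_length) {
    warning("recording shorter than one window; no windows emitted")
    return(list())
  }
  n_win <- floor((duration - spec$window_length) / spec$hop) + 1
  starts <- (seq_len(n_win) - 1) * spec$hop

  lapply(starts, function(t0) {
    t1 <- t0 + spec$window_length
    channels <- lapply(signals, function(s) {
      # indices i with t0 <= (i-1)/fs < t1
      i0 <- ceiling(t0 * s$sampling_rate - 1e-9) + 1
      i1 <- ceiling(t1 * s$sampling_rate - 1e-9)
      s$samples[i0:min(i1, length(s$samples))]
    })
    fs <- vapply(signals, function(s) s$sampling_rate, numeric(1))
    structure(
      list(channels = channels, fs = fs, start = t0, end = t1,
           label = if (is.null(label_fun)) NA_real_ else label_fun(t1),
           subject_id = subject_id),
      class = "windowed_segment"
    )
  })
}

#' @export
print.windowed_segment <- function(x, ...) {
  cat(sprintf("windowed_segment [%g, %g) s, subject %s, label %s; %s\n",
              x$start, x$end, x$subject_id,
              ifelse(is.na(x$label), "-", format(x$label)),
              paste(sprintf("%s: %d", names(x$channels),
                            lengths(x$channels)), collapse = ", ")))
  invisible(x)
}

#' Read / write a windowed feature table
#'
#' Feature tables are plain CSV with a header row and fixed leading columns
#' `subject_id`, `window_start`, `window_end`, `label`, followed by one
#' column per extracted feature (see [feature_names()]).
#'
#' @param path CSV path.
#' @return `read_feature_table`: a `data.frame`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_feature_table
#' @param table a feature `data.frame`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
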