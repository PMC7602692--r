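#' Construct a plantar-pressure recording
#'
#' A recording is one bout of one activity by one subject: 14 parallel force
#' series (7 sites x left/right foot) in newtons at a common sampling rate.
#'
#' @param channels numeric matrix, `n_samples` rows and 14 columns named
#'   `L1..L7,R1..R7` (see [channel_names()]).
#' @param subject_id character scalar.
#' @param activity one of [activities()].
#' @param sampling_rate sampling frequency in Hz (default 100).
#' @return An object of class `pressure_recording`.
#' @export
pressure_recording <- function(channels, subject_id, activity,
                               sampling_rate = 100) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 14L) {
    stop("recording must have exactly 14 channels, got ", ncol(channels))
  }
  if (is.null(colnames(channels))) colnames(channels) <- channel_names()
  if (!identical(colnames(channels), channel_names())) {
    channels <- channels[, channel_names(), drop = FALSE]
  }
  if (nrow(channels) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(channels))) stop("forces must be finite")
  if (!activity %in% activities()) {
    stop("unknown activity label: ", activity)
  }
  structure(
    list(subject_id = as.character(subject_id), activity = activity,
         sampling_rate = sampling_rate, channels = channels,
         n_samples = nrow(channels)),
    class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf("<pressure_recording> subject %s, activity %s: %d samples (%.1f s at %g Hz), 14 channels\n",
              x$subject_id, x$activity, x$n_samples,
              x$n_samples / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

#' Force-sensor calibration curves
#'
#' Maps raw 12-bit ADC counts (0-4095) to force in newtons. The curve must be
#' monotone non-decreasing over the ADC range; calibrated output is clipped
#' below at 0 N. `linear_calibration` is a gain/offset line;
#' `lookup_calibration` interpolates a measured (ADC, newton) table.
#'
#' @param gain newtons per ADC count; must be >= 0.
#' @param offset newtons added after the gain (default 0).
#' @return An object of class `pressure_calibration`.
#' @export
#' @examples
#' cal <- linear_calibration(gain = 20 / 4095)
#' convert_to_newtons(c(0, 4095), cal)
linear_calibration <- function(gain, offset = 0) {
  if (gain < 0) stop("calibration must be monotone non-decreasing: gain < 0")
  structure(list(type = "linear",
                 fun = function(raw) gain * raw + offset),
            class = "pressure_calibration")
}

#' @param adc,newtons paired vectors defining a piecewise-linear curve;
#'   `newtons` must be non-decreasing in `adc` order.
#' @rdname linear_calibration
#' @export
lookup_calibration <- function(adc, newtons) {
  o <- order(adc)
  adc <- adc[o]; newtons <- newtons[o]
  if (any(diff(newtons) < 0)) {
    stop("calibration must be monotone non-decreasing over the ADC range")
  }
  structure(list(type = "lookup",
                 fun = function(raw) {
                   stats::approx(adc, newtons, xout = raw, rule = 2)$y
                 }),
            class = "pressure_calibration")
}

#' Convert raw ADC counts to newtons
#'
#' @param raw numeric vector of 12-bit ADC counts in \[0, 4095\].
#' @param calibration a [linear_calibration()] or [lookup_calibration()].
#' @return Numeric force series in newtons, clipped below at 0.
#' @export
convert_to_newtons <- function(raw, calibration) {
  if (!inherits(calibration, "pressure_calibration")) {
    stop("calibration must be a 'pressure_calibration' object")
  }
  if (any(raw < 0 | raw > 4095)) stop("raw ADC values must lie in [0, 4095]")
  pmax(0, calibration$fun(raw))
}

#' Zero-phase low-pass smoothing
#'
#' Second-order low-pass Butterworth filter (default cutoff 5 Hz), applied
#' forward and backward (`signal::filtfilt`) so the response is zero-phase and
#' peak timing is preserved. The effective magnitude response is the square of
#' the single-pass Butterworth response; DC gain is exactly 1.
#'
#' @param series numeric force series.
#' @param sampling_rate Hz, must exceed 10.
#' @param cutoff_hz cutoff frequency (default 5).
#' @param order filter order (default 2).
#' @return Smoothed series, same length as the input.
#' @importFrom signal butter filtfilt
#' @export
lowpass_smooth <- function(series, sampling_rate, cutoff_hz = 5, order = 2) {
  if (sampling_rate <= 10) stop("sampling_rate must exceed 10 Hz")
  if (length(series) < 3 * order) {
    stop("series too short to filter: need at least ", 3 * order, " samples")
  }
  bf <- signal::butter(order, cutoff_hz / (sampling_rate / 2), type = "low")
  # odd-reflection padding keeps startup transients out of the output and
  # makes the DC gain exact; padding length covers many filter time constants
  n <- length(series)
  pad <- min(n - 1L, max(24L, as.integer(ceiling(10 * sampling_rate / cutoff_hz))))
  pre <- 2 * series[1] - series[seq(pad + 1L, 2L)]
  post <- 2 * series[n] - series[seq(n - 1L, n - pad)]
  sm <- signal::filtfilt(bf, c(pre, series, post))
  as.numeric(sm[pad + seq_len(n)])
}

#' Segment a recording into half-overlapping windows
#'
#' Consecutive windows advance by half the window length (50% overlap); a
#' trailing fragment shorter than one full window is discarded. A recording
#' shorter than one window yields zero windows.
#'
#' @param rec a [pressure_recording()], or an integer sample count.
#' @param length_s window length in seconds; `length_s * sampling_rate` must
#'   be an even integer so the stride is a whole number of samples.
#' @param sampling_rate used only when `rec` is a bare sample count.
#' @return Data frame with columns `start`, `end` (1-based inclusive sample
#'   indices) and `start_s` (window start time in seconds); zero rows when the
#'   recording is too short.
#' @export
#' @examples
#' nrow(segment_windows(24000, 20))  # 240 s at 100 Hz, 20 s windows -> 23
segment_windows <- function(rec, length_s, sampling_rate = 100) {
  if (inherits(rec, "pressure_recording")) {
    n <- rec$n_samples
    sampling_rate <- rec$sampling_rate
  } else {
    n <- as.integer(rec)
  }
  L <- length_s * sampling_rate
  if (abs(L - round(L)) > 1e-9) stop("length_s x sampling_rate must be an integer")
  L <- as.integer(round(L))
  if (L %% 2L != 0L) stop("window length in samples must be even (stride = L/2)")
  stride <- L %/% 2L
  if (n < L) {
    return(data.frame(start = integer(0), end = integer(0),
                      start_s = numeric(0)))
  }
  k <- (n - L) %/% stride + 1L
  start <- 1L + stride * (seq_len(k) - 1L)
  data.frame(start = start, end = start + L - 1L,
             start_s = (start - 1L) / sampling_rate)
}

#' Read a cohort of recordings from a manifest
#'
#' The manifest is a CSV with columns `subject_id,activity,file`; each file is
#' a CSV with 14 numeric channel columns `L1..L7,R1..R7` plus an optional
#' leading time column `t`. One recording is produced per manifest row; bouts
#' split across files remain separate recordings (never concatenated across
#' the gap).
#'
#' @param manifest_path path to the manifest CSV.
#' @param data_dir directory the manifest's `file` column is relative to
#'   (default: the manifest's own directory).
#' @param sampling_rate Hz (default 100).
#' @return List of [pressure_recording()] objects.
#' @export
read_recordings <- function(manifest_path, data_dir = dirname(manifest_path),
                            sampling_rate = 100) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "activity", "file")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns subject_id, activity, file")
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    path <- file.path(data_dir, row$file)
    if (!file.exists(path)) {
      stop(sprintf("manifest row %d: file not found: %s", i, path))
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    cols <- setdiff(names(df), "t")
    if (length(cols) != 14L) {
      stop(sprintf("schema error in %s (manifest row %d): expected 14 channel columns, found %d",
                   row$file, i, length(cols)))
    }
    mat <- matrix(NA_real_, nrow(df), 14L, dimnames = list(NULL, cols))
    for (j in seq_along(cols)) {
      v <- df[[cols[j]]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("parse error in %s, column %s, line %d: non-numeric value '%s'",
                     row$file, cols[j], bad[1] + 1L, v[bad[1]]))
      }
      mat[, j] <- num
    }
    pressure_recording(mat, row$subject_id, row$activity, sampling_rate)
  })
}

#' Write recordings and a manifest as CSV
#'
#' Writes one CSV per recording (columns `t,L1..L7,R1..R7`) plus a
#' `manifest.csv`, the dialect [read_recordings()] reads. Forces are written
#' with 17 significant digits so a write-read round trip reproduces every
#' sample exactly.
#'
#' @param recordings list of [pressure_recording()] objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_recordings <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    fname <- sprintf("%s_%s_%03d.csv", rec$subject_id, rec$activity, i)
    tcol <- (seq_len(rec$n_samples) - 1) / rec$sampling_rate
    body <- cbind(format(tcol, trim = TRUE),
                  apply(rec$channels, 2, function(col) {
                    sprintf("%.17g", col)
                  }))
    con <- file(file.path(dir, fname), "w")
    writeLines(paste(c("t", channel_names()), collapse = ","), con)
    writeLines(apply(body, 1, paste, collapse = ","), con)
    close(con)
    fname
  }, character(1))
  manifest <- data.frame(
    subject_id = vapply(recordings, `[[`, "", "subject_id"),
    activity = vapply(recordings, `[[`, "", "activity"),
    file = rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
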