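#' Tuning parameters for feature extraction
#'
#' @param contact_rel stance/contact threshold as a fraction of the foot
#'   envelope's maximum within the window (default 0.05).
#' @param contact_floor absolute floor on the contact threshold in newtons
#'   (default 0.4, twice the 0.2 N sensing floor of the insole's
#'   force-sensing resistors).
#' @param peak_rel_height fraction of peak height at which peak widths are
#'   measured (default 0.30).
#' @param freq_band AC band, in Hz, over which spectral power density is
#'   averaged (default `c(0.05, 50)`).
#' @return A list of class `feature_control`.
#' @export
feature_control <- function(contact_rel = 0.05, contact_floor = 0.4,
                            peak_rel_height = 0.30,
                            freq_band = c(0.05, 50)) {
  structure(list(contact_rel = contact_rel, contact_floor = contact_floor,
                 peak_rel_height = peak_rel_height, freq_band = freq_band),
            class = "feature_control")
}

#' General statistics of a force series
#'
#' Mean, maximum, standard deviation (population convention, divide by n),
#' and median.
#'
#' @param series non-empty numeric series.
#' @return Named numeric vector `mean`, `max`, `sd`, `median`.
#' @export
general_statistics <- function(series) {
  if (length(series) < 1L) stop("series must be non-empty")
  c(mean = mean(series), max = max(series), sd = pop_sd(series),
    median = median(series))
}

#' Detect peaks in a force series
#'
#' Local maxima with no height or prominence threshold; a plateau higher
#' than both neighbours counts as one peak at its midpoint. Each peak's
#' width is the duration of the maximal contiguous interval containing it
#' on which the series stays at or above `rel_height` times the peak
#' magnitude (absolute height, not prominence).
#'
#' @param series non-empty numeric series.
#' @param sampling_rate Hz.
#' @param rel_height width threshold as a fraction of peak height
#'   (default 0.30).
#' @return A list of class `peak_set`: `indices` (1-based, strictly
#'   increasing), `magnitudes` (N), `widths` (s), `intervals` (s, between
#'   consecutive peaks).
#' @export
detect_peaks <- function(series, sampling_rate, rel_height = 0.30) {
  if (length(series) < 1L) stop("series must be non-empty")
  ps <- .peak_scan(as.numeric(series), rel_height)
  structure(list(indices = ps$indices, magnitudes = ps$magnitudes,
                 widths = ps$width_samples / sampling_rate,
                 intervals = diff(ps$indices) / sampling_rate),
            class = "peak_set")
}

#' Summarize a peak set into seven scalar features
#'
#' Peak count, mean and SD of inter-peak intervals, mean and SD of peak
#' magnitudes, mean and SD of peak widths. Statistics that are undefined for
#' the peak set at hand (no peaks, or no intervals) are set to 0.
#'
#' @param ps a [detect_peaks()] result.
#' @return Named numeric vector of length 7.
#' @export
peak_features <- function(ps) {
  stopifnot(inherits(ps, "peak_set"))
  mz <- function(x) if (length(x) >= 1L) mean(x) else 0
  sz <- function(x) if (length(x) >= 1L) pop_sd(x) else 0
  c(n = length(ps$indices),
    interval_mean = mz(ps$intervals), interval_sd = sz(ps$intervals),
    mag_mean = mz(ps$magnitudes), mag_sd = sz(ps$magnitudes),
    width_mean = mz(ps$widths), width_sd = sz(ps$widths))
}

# contact threshold for one foot envelope within a window
contact_threshold <- function(env, control) {
  max(control$contact_rel * max(env), control$contact_floor)
}

# interior runs of `flag` (TRUE segments not touching the window border)
interior_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < length(flag)
  data.frame(start = starts[keep], end = ends[keep])
}

#' Gait-phase features of a window
#'
#' Works on the per-foot envelope (pointwise maximum over the foot's
#' available channels). Contact is declared where the envelope exceeds a
#' threshold (5% of the window's envelope maximum, floored at 0.4 N). A
#' "full" stance phase is a contact segment entirely inside the window.
#'
#' Two features: (1) the force difference between foot landing and foot
#' lift — per stance, the first envelope peak in the early half minus the
#' last peak in the late half — averaged over all full stances of both
#' feet; (2) the mean duration of double-float intervals, i.e. interior
#' intervals during which neither foot is in contact. Windows with no full
#' stance (or no float interval) yield 0 for the respective feature.
#'
#' @param env_left,env_right per-foot envelope series.
#' @param sampling_rate Hz.
#' @param control a [feature_control()].
#' @return Named numeric vector `landing_lift_diff`, `double_float_s`.
#' @export
gait_phase_features <- function(env_left, env_right, sampling_rate,
                                control = feature_control()) {
  stopifnot(length(env_left) == length(env_right))
  thr_l <- contact_threshold(env_left, control)
  thr_r <- contact_threshold(env_right, control)

  stance_diffs <- function(env, thr) {
    segs <- interior_runs(env >= thr)
    if (nrow(segs) == 0L) return(numeric(0))
    vapply(seq_len(nrow(segs)), function(i) {
      x <- env[segs$start[i]:segs$end[i]]
      m <- length(x)
      h <- ceiling(m / 2)
      pk <- .peak_scan(x, 0.5)$indices
      early <- if (any(pk <= h)) x[pk[pk <= h][1]] else max(x[1:h])
      late_half <- (m - h + 1L):m
      late <- if (any(pk >= m - h + 1L)) {
        x[pk[pk >= m - h + 1L][length(pk[pk >= m - h + 1L])]]
      } else max(x[late_half])
      early - late
    }, numeric(1))
  }
  diffs <- c(stance_diffs(env_left, thr_l), stance_diffs(env_right, thr_r))
  landing_lift <- if (length(diffs)) mean(diffs) else 0

  off <- interior_runs(env_left < thr_l & env_right < thr_r)
  double_float <- if (nrow(off)) {
    mean(off$end - off$start + 1L) / sampling_rate
  } else 0
  c(landing_lift_diff = landing_lift, double_float_s = double_float)
}

#' Frequency-domain features of a window
#'
#' Computed on the one-sided magnitude spectrum of the sum of all available
#' channels. The AC component excludes the 0 Hz bin; band edges are
#' inclusive. The five features: (1) power density, the mean squared
#' spectral magnitude over the 0.05-50 Hz AC band; (2) the
#' magnitude-weighted mean frequency over 1.67-10 Hz; (3) the skewness of
#' the spectral magnitudes strictly below 10 Hz; (4) and (5) the mean and
#' SD of the AC magnitudes from 2 to 10 Hz. Degenerate spectra (e.g. a
#' constant signal) yield 0 for the affected features.
#'
#' @param summed sum of all available channel series over the window.
#' @param sampling_rate Hz.
#' @param control a [feature_control()].
#' @return Named numeric vector of length 5.
#' @export
frequency_features <- function(summed, sampling_rate,
                               control = feature_control()) {
  n <- length(summed)
  if (n < sampling_rate) stop("window must span at least 1 s for spectral features")
  amp <- 2 * Mod(stats::fft(summed)) / n
  k <- seq_len(n %/% 2 + 1L)          # one-sided spectrum, DC..Nyquist
  f <- (k - 1L) * sampling_rate / n
  amp <- amp[k]
  amp[amp < 1e-10 * max(amp)] <- 0    # suppress FFT round-off dust
  ac <- f > 0
  band <- ac & f >= control$freq_band[1] & f <= control$freq_band[2]
  power_density <- if (any(band)) mean(amp[band]^2) else 0
  sel_w <- f >= 1.67 & f <= 10
  wsum <- sum(amp[sel_w])
  wmean <- if (wsum > 0) sum(f[sel_w] * amp[sel_w]) / wsum else 0
  sel_sk <- ac & f < 10
  skew <- if (any(sel_sk)) pop_skewness(amp[sel_sk]) else 0
  sel_ac <- f >= 2 & f <= 10
  c(power_density = power_density, wmean_1.67_10hz = wmean,
    skew_below_10hz = skew,
    ac_mean_2_10hz = if (any(sel_ac)) mean(amp[sel_ac]) else 0,
    ac_sd_2_10hz = if (any(sel_ac)) pop_sd(amp[sel_ac]) else 0)
}

# Pearson correlation with zero-variance pairs defined as 0
safe_cor <- function(x, y) {
  if (pop_sd(x) == 0 || pop_sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Pressure-distribution features of a window
#'
#' The anterior-posterior (AP) block compares the forefoot envelope
#' (pointwise maximum over the available forefoot sites 4-7) with the heel
#' sensor: the mean forefoot-minus-heel difference averaged over the two
#' feet (1 feature) and the Pearson correlation between the two series for
#' each foot (2 features). The medial-lateral (ML) block does the same for
#' the medial (site 6) versus lateral (site 4) forefoot sensors. Blocks are
#' only defined when the configuration supplies their sites; correlations of
#' zero-variance series are defined as 0.
#'
#' @param channels numeric matrix of the window's channels, columns named as
#'   in [channel_names()] (only the configuration's channels are required).
#' @param config a [sensor_config()] or site vector.
#' @return Named numeric vector: `ap_diff`, `ap_cor.L`, `ap_cor.R` when the
#'   AP block is available, then `ml_diff`, `ml_cor.L`, `ml_cor.R` when the
#'   ML block is available (possibly length 0).
#' @export
pressure_distribution_features <- function(channels, config) {
  config <- as_sensor_config(config)
  sites <- config$sites
  out <- numeric(0)
  if (ap_available(sites)) {
    fore <- intersect(4:7, sites)
    vals <- lapply(c("L", "R"), function(foot) {
      heel <- channels[, paste0(foot, 1)]
      env <- do.call(pmax, as.data.frame(
        channels[, paste0(foot, fore), drop = FALSE]))
      list(diff = mean(env) - mean(heel), cor = safe_cor(env, heel))
    })
    out <- c(out,
             ap_diff = mean(c(vals[[1]]$diff, vals[[2]]$diff)),
             ap_cor.L = vals[[1]]$cor, ap_cor.R = vals[[2]]$cor)
  }
  if (ml_available(sites)) {
    vals <- lapply(c("L", "R"), function(foot) {
      lat <- channels[, paste0(foot, 4)]
      med <- channels[, paste0(foot, 6)]
      list(diff = mean(med) - mean(lat), cor = safe_cor(lat, med))
    })
    out <- c(out,
             ml_diff = mean(c(vals[[1]]$diff, vals[[2]]$diff)),
             ml_cor.L = vals[[1]]$cor, ml_cor.R = vals[[2]]$cor)
  }
  out
}

#' Extract the full feature vector of one window
#'
#' Assembles exactly the features [feature_catalog()] lists for the
#' configuration, in catalog order: per-channel general statistics and peak
#' analysis, then gait-phase, frequency-domain, and pressure-distribution
#' features. 167 features at the full 7-sensor configuration.
#'
#' @param channels numeric matrix (window samples x channels) with columns
#'   named as in [channel_names()]; must contain the configuration's
#'   channels.
#' @param config a [sensor_config()] or site vector.
#' @param sampling_rate Hz.
#' @param control a [feature_control()].
#' @return Named numeric vector, names equal to the catalog's `feature_id`.
#' @export
extract_features <- function(channels, config, sampling_rate = 100,
                             control = feature_control()) {
  config <- as_sensor_config(config)
  sites <- config$sites
  chans <- channel_names(sites)
  missing <- setdiff(chans, colnames(channels))
  if (length(missing)) {
    stop("window is missing channels: ", paste(missing, collapse = ", "))
  }
  gs <- unlist(lapply(chans, function(ch) {
    v <- general_statistics(channels[, ch])
    names(v) <- sprintf("gs.%s.%s", names(v), ch)
    v
  }))
  pk <- unlist(lapply(chans, function(ch) {
    v <- peak_features(detect_peaks(channels[, ch], sampling_rate,
                                    control$peak_rel_height))
    names(v) <- sprintf("pk.%s.%s", names(v), ch)
    v
  }))
  env_l <- do.call(pmax, as.data.frame(
    channels[, paste0("L", sites), drop = FALSE]))
  env_r <- do.call(pmax, as.data.frame(
    channels[, paste0("R", sites), drop = FALSE]))
  gait <- gait_phase_features(env_l, env_r, sampling_rate, control)
  names(gait) <- paste0("gait.", names(gait))
  fr <- frequency_features(rowSums(channels[, chans, drop = FALSE]),
                           sampling_rate, control)
  names(fr) <- paste0("freq.", names(fr))
  dist <- pressure_distribution_features(channels, config)
  if (length(dist)) names(dist) <- paste0("dist.", names(dist))
  out <- c(gs, pk, gait, fr, dist)
  catalog <- feature_catalog(config)
  stopifnot(identical(names(out), catalog$feature_id))
  out
}

#' Extract the feature matrix of a cohort
#'
#' Smooths every channel (zero-phase 5 Hz Butterworth), segments each
#' recording into half-overlapping windows, and extracts the configuration's
#' feature vector for every window.
#'
#' @param recordings list of [pressure_recording()] objects.
#' @param config a [sensor_config()] or site vector.
#' @param window_s window length in seconds.
#' @param control a [feature_control()].
#' @param smooth apply [lowpass_smooth()] before windowing (default TRUE).
#' @return Data frame with columns `subject_id`, `activity`,
#'   `window_start_s`, followed by one column per feature; attribute
#'   `feature_ids` names the feature columns.
#' @export
extract_feature_matrix <- function(recordings, config, window_s,
                                   control = feature_control(),
                                   smooth = TRUE) {
  config <- as_sensor_config(config)
  chans <- channel_names(config$sites)
  per_rec <- lapply(recordings, function(rec) {
    wins <- segment_windows(rec, window_s)
    if (nrow(wins) == 0L) return(NULL)
    mat <- rec$channels[, chans, drop = FALSE]
    if (smooth) {
      mat <- apply(mat, 2, lowpass_smooth, sampling_rate = rec$sampling_rate)
      colnames(mat) <- chans
    }
    feats <- t(vapply(seq_len(nrow(wins)), function(i) {
      extract_features(mat[wins$start[i]:wins$end[i], , drop = FALSE],
                       config, rec$sampling_rate, control)
    }, numeric(count_features(config))))
    cbind(data.frame(subject_id = rec$subject_id, activity = rec$activity,
                     window_start_s = wins$start_s,
                     stringsAsFactors = FALSE),
          as.data.frame(feats))
  })
  out <- do.call(rbind, per_rec)
  rownames(out) <- NULL
  attr(out, "feature_ids") <- feature_catalog(config)$feature_id
  attr(out, "config") <- config
  out
}

#' Feature columns of a feature matrix
#'
#' @param fm a [extract_feature_matrix()] result (or any data frame whose
#'   non-feature columns are `subject_id`, `activity`, `window_start_s`).
#' @return Character vector of feature column names.
#' @export
feature_ids <- function(fm) {
  ids <- attr(fm, "feature_ids")
  if (is.null(ids)) {
    ids <- setdiff(names(fm), c("subject_id", "activity", "window_start_s"))
  }
  ids
}
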