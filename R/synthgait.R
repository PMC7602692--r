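#' Generative profile for one activity
#'
#' Describes how one activity loads the 14 pressure channels. Gait
#' activities (`cadence_hz > 0`) produce alternating-foot stance pulses: a
#' trapezoidal body-weight base (rapid 0.01 s ramps) plus one raised-cosine
#' bump per site, whose center and width are expressed as fractions of the
#' stance duration (heel bumps early in stance, forefoot/toe bumps late).
#' Running inserts a flight interval with both feet at the noise floor
#' (`flight_fraction` of the cycle per flight; stance is then
#' `0.5 - flight_fraction` of the cycle). Static activities
#' (`cadence_hz = 0`) produce a constant per-site load plus low-frequency
#' postural sway. Mixed activities concatenate bouts of other profiles via
#' `bout_mixture`.
#'
#' @param activity one of [activities()].
#' @param cadence_hz gait-cycle rate in Hz (0 for static activities).
#' @param stance_fraction fraction of the cycle each foot is in contact.
#' @param flight_fraction fraction of the cycle with both feet off the
#'   ground (running); positive values force
#'   `stance_fraction = 0.5 - flight_fraction`.
#' @param site_amp length-7 non-negative vector: peak bump force per site (N).
#' @param site_phase length-7 vector in \[0, 1\]: bump center within stance.
#' @param site_width bump full width as a fraction of stance (scalar or
#'   length 7).
#' @param static_load length-7 vector: constant per-site force (N) for
#'   static activities.
#' @param base_load body-weight base force during stance (N), applied to all
#'   loaded sites.
#' @param sway_amp,sway_hz amplitude (N) and rate of postural sway.
#' @param noise_sd additive Gaussian noise SD (N).
#' @param bout_mixture optional list of `list(profile =, min_s =, max_s =)`
#'   cycled to fill the recording (mixed activities such as office work).
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(activity, cadence_hz = 0, stance_fraction = 0.6,
                             flight_fraction = 0,
                             site_amp = rep(0, 7), site_phase = rep(0.5, 7),
                             site_width = 0.5, static_load = rep(0, 7),
                             base_load = 1.5, sway_amp = 0, sway_hz = 0.25,
                             noise_sd = 0.1, bout_mixture = NULL) {
  if (stance_fraction < 0 || stance_fraction > 1) {
    stop("stance_fraction must lie in [0, 1]")
  }
  if (flight_fraction > 0 && cadence_hz <= 0) {
    stop("flight_fraction > 0 requires cadence_hz > 0")
  }
  if (flight_fraction > 0) stance_fraction <- 0.5 - flight_fraction
  if (any(site_amp < 0) || any(static_load < 0)) {
    stop("site amplitudes and static loads must be non-negative")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(site_width) == 1L) site_width <- rep(site_width, 7)
  structure(list(activity = activity, cadence_hz = cadence_hz,
                 stance_fraction = stance_fraction,
                 flight_fraction = flight_fraction,
                 site_amp = site_amp, site_phase = site_phase,
                 site_width = site_width, static_load = static_load,
                 base_load = base_load, sway_amp = sway_amp,
                 sway_hz = sway_hz, noise_sd = noise_sd,
                 bout_mixture = bout_mixture),
            class = "activity_profile")
}

#' Subject-level variation
#'
#' @param weight_scale multiplicative factor on all forces (> 0).
#' @param cadence_offset additive shift on gait-cycle rates (Hz).
#' @param seed integer seed controlling the recording's randomness.
#' @return An object of class `subject_effect`.
#' @export
subject_effect <- function(weight_scale = 1, cadence_offset = 0,
                           seed = NULL) {
  if (weight_scale <= 0) stop("weight_scale must be positive")
  structure(list(weight_scale = weight_scale,
                 cadence_offset = cadence_offset, seed = seed),
            class = "subject_effect")
}

#' Default activity profiles
#'
#' One generative profile per activity class. Gait classes differ in cadence
#' and in how load is distributed between heel and forefoot over the stance:
#' level walking is heel-first then forefoot push-off; slope walking shifts
#' amplitude toward the forefoot; upstairs is forefoot-led with a weak late
#' heel; downstairs has a sharp early forefoot landing; running is faster,
#' heavier, and includes a 10% flight phase. Cycling loads the forefoot
#' rhythmically at low force. Sitting and standing are static at low and
#' high load; office work mixes standing bouts with short walks.
#'
#' @param noise_sd additive noise SD (N) applied to every profile.
#' @return Named list of [activity_profile()] objects, one per
#'   [activities()] entry.
#' @export
default_activity_profiles <- function(noise_sd = 0.1) {
  standing <- activity_profile(
    "standing", static_load = c(7, 2.5, 2, 4, 5, 4.5, 2),
    sway_amp = 0.8, sway_hz = 0.25, noise_sd = noise_sd)
  walking <- activity_profile(
    "walking_flat", cadence_hz = 0.95, stance_fraction = 0.62,
    site_amp = c(12, 3, 2.5, 6, 9, 7, 5),
    site_phase = c(0.22, 0.40, 0.40, 0.65, 0.70, 0.72, 0.82),
    site_width = 0.5, noise_sd = noise_sd)
  list(
    sitting = activity_profile(
      "sitting", static_load = c(0.25, 0.10, 0.10, 0.15, 0.20, 0.15, 0.10),
      sway_amp = 0.05, noise_sd = noise_sd),
    standing = standing,
    walking_flat = walking,
    walking_upstairs = activity_profile(
      "walking_upstairs", cadence_hz = 0.72, stance_fraction = 0.65,
      site_amp = c(4, 2.5, 2, 8, 11, 9, 7),
      site_phase = c(0.60, 0.45, 0.45, 0.30, 0.32, 0.30, 0.50),
      site_width = 0.5, noise_sd = noise_sd),
    walking_downstairs = activity_profile(
      "walking_downstairs", cadence_hz = 0.85, stance_fraction = 0.55,
      site_amp = c(6, 3, 2.5, 12, 14, 10, 4),
      site_phase = c(0.60, 0.45, 0.40, 0.15, 0.18, 0.20, 0.50),
      site_width = 0.35, noise_sd = noise_sd),
    walking_slope = activity_profile(
      "walking_slope", cadence_hz = 0.88, stance_fraction = 0.63,
      site_amp = c(9, 3, 2.5, 8, 12, 10, 8),
      site_phase = c(0.20, 0.40, 0.45, 0.70, 0.72, 0.75, 0.85),
      site_width = 0.5, noise_sd = noise_sd),
    running = activity_profile(
      "running", cadence_hz = 1.4, flight_fraction = 0.10,
      site_amp = c(16, 4, 3.5, 10, 14, 12, 9),
      site_phase = c(0.20, 0.35, 0.35, 0.55, 0.58, 0.60, 0.72),
      site_width = 0.55, base_load = 4, noise_sd = noise_sd),
    cycling = activity_profile(
      "cycling", cadence_hz = 0.9, stance_fraction = 0.5,
      site_amp = c(0.3, 0.8, 0.8, 3, 4, 3.5, 2),
      site_phase = rep(0.5, 7), site_width = 0.8, base_load = 0.8,
      noise_sd = noise_sd),
    office_work = activity_profile(
      "office_work", noise_sd = noise_sd,
      bout_mixture = list(
        list(profile = standing, min_s = 8, max_s = 15),
        list(profile = walking, min_s = 3, max_s = 6))))
}

# deterministic noiseless channel matrix for one profile segment
simulate_segment <- function(profile, effect, t, sampling_rate) {
  n <- length(t)
  mat <- matrix(0, n, 14L, dimnames = list(NULL, channel_names()))
  ws <- effect$weight_scale
  if (profile$cadence_hz > 0) {
    cad <- max(profile$cadence_hz + effect$cadence_offset, 0.2)
    period <- 1 / cad
    S <- profile$stance_fraction * period
    ramp <- 0.01
    for (foot in c("L", "R")) {
      offset <- if (foot == "L") 0 else period / 2
      u <- (t - offset) %% period
      in_stance <- u < S
      base <- profile$base_load * pmin(1, u / ramp, (S - u) / ramp)
      base[!in_stance | base < 0] <- 0
      for (s in 1:7) {
        amp <- profile$site_amp[s]
        x <- base
        if (amp > 0) {
          ctr <- profile$site_phase[s] * S
          w <- profile$site_width[s] * S / 2
          d <- u - ctr
          hit <- abs(d) <= w & in_stance
          x[hit] <- x[hit] + amp * 0.5 * (1 + cos(pi * d[hit] / w))
        }
        mat[, paste0(foot, s)] <- ws * x
      }
    }
  } else {
    for (foot in c("L", "R")) {
      sway_phase <- if (foot == "L") 0 else pi
      rel <- if (max(profile$static_load) > 0) {
        profile$static_load / max(profile$static_load)
      } else rep(0, 7)
      sway <- profile$sway_amp * sin(2 * pi * profile$sway_hz * t + sway_phase)
      for (s in 1:7) {
        mat[, paste0(foot, s)] <- ws * (profile$static_load[s] + rel[s] * sway)
      }
    }
  }
  mat
}

#' Simulate one plantar-pressure recording
#'
#' Deterministic given the profile and the effect's seed. Forces are
#' clipped at 0 N after additive noise.
#'
#' @param profile an [activity_profile()].
#' @param effect a [subject_effect()].
#' @param duration_s recording length in seconds.
#' @param sampling_rate Hz (default 100).
#' @return A [pressure_recording()] with 14 channels.
#' @export
#' @examples
#' rec <- simulate_recording(default_activity_profiles()$walking_flat,
#'                           subject_effect(seed = 1), duration_s = 20)
#' rec
simulate_recording <- function(profile, effect = subject_effect(),
                               duration_s, sampling_rate = 100) {
  if (!inherits(profile, "activity_profile")) stop("invalid profile")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!is.null(effect$seed)) set.seed(effect$seed)
  n <- as.integer(round(duration_s * sampling_rate))
  t <- (seq_len(n) - 1L) / sampling_rate
  if (!is.null(profile$bout_mixture)) {
    mat <- matrix(0, n, 14L, dimnames = list(NULL, channel_names()))
    pos <- 0L
    k <- 0L
    while (pos < n) {
      part <- profile$bout_mixture[[k %% length(profile$bout_mixture) + 1L]]
      len <- as.integer(round(
        stats::runif(1, part$min_s, part$max_s) * sampling_rate))
      take <- min(len, n - pos)
      seg_t <- (seq_len(take) - 1L) / sampling_rate
      mat[pos + seq_len(take), ] <-
        simulate_segment(part$profile, effect, seg_t, sampling_rate)
      pos <- pos + take
      k <- k + 1L
    }
  } else {
    mat <- simulate_segment(profile, effect, t, sampling_rate)
  }
  if (profile$noise_sd > 0) {
    mat <- mat + matrix(stats::rnorm(length(mat), 0, profile$noise_sd),
                        nrow(mat), ncol(mat))
  }
  mat <- pmax(mat, 0)
  pressure_recording(mat, subject_id = "sim", activity = profile$activity,
                     sampling_rate = sampling_rate)
}

#' Default recording durations per activity
#'
#' Four minutes per activity, except level walking and running which run
#' eight minutes (matching the longer bouts typical of those tasks).
#'
#' @param base_s default bout duration (s).
#' @param long_s duration for `walking_flat` and `running` (s).
#' @return Named numeric vector over [activities()].
#' @export
default_durations <- function(base_s = 240, long_s = 480) {
  d <- stats::setNames(rep(base_s, 9), activities())
  d[c("walking_flat", "running")] <- long_s
  d
}

#' Simulate a labeled cohort
#'
#' Draws per-subject weight and cadence effects, then one recording per
#' (subject, activity) pair. All randomness flows from `master_seed`.
#' Optional dropout reproduces incomplete participation: element `i` of
#' `n_activities` is the number of activities subject `i` completed; the
#' dropped activities are chosen uniformly at random.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param profiles named list of nine [activity_profile()]s.
#' @param durations named vector of bout durations in seconds (see
#'   [default_durations()]).
#' @param master_seed integer seed for the whole cohort.
#' @param n_activities optional integer vector (length `n_subjects`): how
#'   many of the nine activities each subject completed.
#' @param weight_log_sd,cadence_sd spread of the subject effects.
#' @return List with `recordings` (list of [pressure_recording()]),
#'   `manifest` (data frame `subject_id`, `activity`), and `effects`.
#' @export
simulate_cohort <- function(n_subjects, profiles = default_activity_profiles(),
                            durations = default_durations(),
                            master_seed = 1, n_activities = NULL,
                            weight_log_sd = 0.12, cadence_sd = 0.05) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  stopifnot(setequal(names(profiles), activities()))
  set.seed(master_seed)
  imax <- .Machine$integer.max
  weight <- stats::rlnorm(n_subjects, 0, weight_log_sd)
  cadoff <- stats::rnorm(n_subjects, 0, cadence_sd)
  subj_ids <- sprintf("S%02d", seq_len(n_subjects))
  if (is.null(n_activities)) n_activities <- rep(9L, n_subjects)
  stopifnot(length(n_activities) == n_subjects)
  done <- lapply(seq_len(n_subjects), function(i) {
    if (n_activities[i] >= 9L) activities()
    else sort(sample(activities(), n_activities[i]))
  })
  rec_seeds <- matrix(sample.int(imax, n_subjects * 9L), n_subjects, 9L,
                      dimnames = list(subj_ids, activities()))
  recordings <- list()
  rows <- list()
  for (i in seq_len(n_subjects)) {
    for (act in done[[i]]) {
      eff <- subject_effect(weight[i], cadoff[i], rec_seeds[i, act])
      rec <- simulate_recording(profiles[[act]], eff, durations[[act]])
      rec$subject_id <- subj_ids[i]
      recordings[[length(recordings) + 1L]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj_ids[i], activity = act, stringsAsFactors = FALSE)
    }
  }
  effects <- data.frame(subject_id = subj_ids, weight_scale = weight,
                        cadence_offset = cadoff)
  list(recordings = recordings, manifest = do.call(rbind, rows),
       effects = effects)
}
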