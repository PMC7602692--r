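#' Sensor configurations
#'
#' A configuration is a non-empty subset of the seven anatomical sensor
#' sites, applied symmetrically to both feet. There are 2^7 - 1 = 127
#' possible configurations.
#'
#' @param sites integer vector of site codes in 1..7.
#' @param label optional human-readable name; defaults to the site list.
#' @return An object of class `sensor_config`.
#' @export
#' @examples
#' count_features(sensor_config(1:7))   # 167
#' count_features(sensor_config(1))     # 29 (heel only)
sensor_config <- function(sites, label = NULL) {
  sites <- sort(unique(as.integer(sites)))
  if (length(sites) < 1L || !all(sites %in% 1:7)) {
    stop("sites must be a non-empty subset of 1..7")
  }
  if (is.null(label)) label <- paste0("{", paste(sites, collapse = ","), "}")
  structure(list(sites = sites, label = label), class = "sensor_config")
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf("<sensor_config> %s (%d sites, %d features): %s\n",
              x$label, length(x$sites), count_features(x),
              paste(site_labels()[as.character(x$sites)], collapse = ", ")))
  invisible(x)
}

as_sensor_config <- function(x) {
  if (inherits(x, "sensor_config")) x else sensor_config(x)
}

#' Enumerate sensor configurations
#'
#' All non-empty subsets of the seven sites up to a maximum size, in a
#' deterministic order (by size, then lexicographically by site list).
#'
#' @param max_sites largest subset size to include, 1..7.
#' @return List of [sensor_config()] objects; 127 when `max_sites = 7`.
#' @export
enumerate_configurations <- function(max_sites = 7) {
  if (max_sites < 1 || max_sites > 7) stop("max_sites must be in 1..7")
  out <- list()
  for (k in seq_len(max_sites)) {
    combos <- utils::combn(7, k)
    for (j in seq_len(ncol(combos))) {
      out[[length(out) + 1L]] <- sensor_config(combos[, j])
    }
  }
  out
}

# availability of the two pressure-distribution blocks
ap_available <- function(sites) 1L %in% sites && any(c(4L, 5L, 6L, 7L) %in% sites)
ml_available <- function(sites) all(c(4L, 6L) %in% sites)

#' Catalog of features a sensor configuration affords
#'
#' Eleven per-channel features (4 general statistics + 7 peak-analysis) are
#' computed for every selected channel on both feet. Two gait-phase and five
#' frequency-domain features are computed from whatever sites are present
#' (foot envelopes and the all-channel sum), so they are always available.
#' The three anterior-posterior pressure-distribution features require the
#' heel (site 1) plus at least one forefoot site (4-7); the three
#' medial-lateral features require both site 4 and site 6. At the full
#' 7-sensor configuration the category sizes are 56 / 98 / 2 / 5 / 6,
#' totalling 167.
#'
#' @param config a [sensor_config()] or site vector.
#' @return Data frame with columns `feature_id`, `category`, `foot`
#'   (`L`/`R`/`NA`), `site` (`NA` for pooled features), in the fixed catalog
#'   order used by [extract_features()].
#' @export
feature_catalog <- function(config) {
  config <- as_sensor_config(config)
  sites <- config$sites
  gs_stats <- c("mean", "max", "sd", "median")
  pk_stats <- c("n", "interval_mean", "interval_sd", "mag_mean", "mag_sd",
                "width_mean", "width_sd")
  rows <- list()
  add <- function(id, cat, foot = NA_character_, site = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_id = id, category = cat, foot = foot, site = site,
      stringsAsFactors = FALSE)
  }
  for (foot in c("L", "R")) for (s in sites) {
    for (st in gs_stats) {
      add(sprintf("gs.%s.%s%d", st, foot, s), "general_statistics", foot, s)
    }
  }
  for (foot in c("L", "R")) for (s in sites) {
    for (st in pk_stats) {
      add(sprintf("pk.%s.%s%d", st, foot, s), "peak_analysis", foot, s)
    }
  }
  add("gait.landing_lift_diff", "gait_phase")
  add("gait.double_float_s", "gait_phase")
  add("freq.power_density", "frequency_domain")
  add("freq.wmean_1.67_10hz", "frequency_domain")
  add("freq.skew_below_10hz", "frequency_domain")
  add("freq.ac_mean_2_10hz", "frequency_domain")
  add("freq.ac_sd_2_10hz", "frequency_domain")
  if (ap_available(sites)) {
    add("dist.ap_diff", "pressure_distribution")
    add("dist.ap_cor.L", "pressure_distribution", "L")
    add("dist.ap_cor.R", "pressure_distribution", "R")
  }
  if (ml_available(sites)) {
    add("dist.ml_diff", "pressure_distribution")
    add("dist.ml_cor.L", "pressure_distribution", "L")
    add("dist.ml_cor.R", "pressure_distribution", "R")
  }
  do.call(rbind, rows)
}

#' Number of features a sensor configuration affords
#'
#' Closed form: `11 * 2 * |sites| + 7 + 3 * [AP block] + 3 * [ML block]`,
#' equal to `nrow(feature_catalog(config))`.
#'
#' @inheritParams feature_catalog
#' @return Integer feature count.
#' @export
count_features <- function(config) {
  config <- as_sensor_config(config)
  sites <- config$sites
  11L * 2L * length(sites) + 7L +
    3L * ap_available(sites) + 3L * ml_available(sites)
}
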