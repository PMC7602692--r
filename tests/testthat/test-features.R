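test_that("general statistics use the population SD convention", {
  expect_equal(unname(general_statistics(rep(4.2, 10))), c(4.2, 4.2, 0, 4.2))
  gs <- general_statistics(c(0, 1, 2, 3))
  expect_equal(unname(gs), c(1.5, 3, sqrt(1.25), 1.5))
  neg <- general_statistics(-c(0, 1, 2, 3))
  expect_equal(neg[["mean"]], -1.5)
  expect_equal(neg[["max"]], 0)
  expect_equal(neg[["sd"]], gs[["sd"]])
  expect_error(general_statistics(numeric(0)), "non-empty")
})

test_that("peak detection matches a brute-force reference on random signals", {
  set.seed(7)
  for (i in 1:40) {
    x <- lowpass_smooth(rnorm(400), 100, cutoff_hz = sample(3:10, 1))
    if (i %% 3 == 0) {  # inject exact plateaus
      x <- round(x, 1)
    }
    ps <- detect_peaks(x, 100)
    expect_equal(ps$indices, brute_peaks(x))
    expect_equal(ps$widths * 100,
                 vapply(ps$indices, function(j) brute_width(x, j), 0))
    expect_true(all(diff(ps$indices) > 0))
    expect_equal(length(ps$intervals), max(0, length(ps$indices) - 1))
  }
})

test_that("peak geometry follows the constructed-signal closed forms", {
  t <- (0:1999) / 100
  # strictly monotone: no interior maxima
  expect_length(detect_peaks(t, 100)$indices, 0)

  # 10 identical raised-cosine pulses, period 2 s
  x <- pulse_train(t, centers = 1 + 2 * (0:9), amp = 5, w = 0.4)
  ps <- detect_peaks(x, 100)
  expect_length(ps$indices, 10)
  expect_equal(mean(ps$intervals), 2.0, tolerance = 1e-9)
  expect_equal(sd(ps$intervals), 0, tolerance = 1e-9)
  expect_equal(mean(ps$magnitudes), 5, tolerance = 1e-6)

  # triangle of base 1 s: the 30%-height chord is 0.7 s wide
  tri <- c(seq(0, 8, length.out = 51), seq(8, 0, length.out = 51)[-1])
  pt <- detect_peaks(tri, 100)
  expect_length(pt$indices, 1)
  expect_lt(abs(pt$widths - 0.7), 0.015)
})

test_that("peak summaries resolve degenerate statistics to zero", {
  empty <- detect_peaks(seq(0, 1, length.out = 50), 100)
  expect_equal(unname(peak_features(empty)), rep(0, 7))

  single <- pulse_train((0:199) / 100, centers = 1, amp = 5, w = 0.1)
  pf <- peak_features(detect_peaks(single, 100))
  expect_equal(pf[["n"]], 1)
  expect_equal(pf[["interval_mean"]], 0)
  expect_equal(pf[["interval_sd"]], 0)
  expect_equal(pf[["mag_mean"]], 5, tolerance = 1e-6)
  expect_equal(pf[["mag_sd"]], 0)
  # raised cosine at 30% height: chord = 2w * acos(-0.4)/pi ~ 0.126 s
  expect_lt(abs(pf[["width_mean"]] - 0.2 * acos(-0.4) / pi), 0.01)
  expect_equal(pf[["width_sd"]], 0)
})

test_that("gait-phase features recover constructed stance timing", {
  # static standing: both envelopes super-threshold throughout -> no float
  coh <- zero_noise_profiles()
  stand <- simulate_recording(coh$standing, subject_effect(seed = 2), 20)
  env <- foot_envelopes(stand)
  g <- gait_phase_features(env$L, env$R, 100)
  expect_equal(g[["double_float_s"]], 0)

  # symmetric stance pulses: landing and lift peaks match
  sym <- activity_profile("walking_flat", cadence_hz = 0.9,
                          stance_fraction = 0.6,
                          site_amp = c(10, 0, 0, 0, 10, 0, 0),
                          site_phase = c(0.25, .5, .5, .5, 0.75, .5, .5),
                          site_width = 0.4, noise_sd = 0)
  rec <- simulate_recording(sym, subject_effect(seed = 3), 20)
  env <- foot_envelopes(rec)
  g <- gait_phase_features(env$L, env$R, 100)
  expect_lt(abs(g[["landing_lift_diff"]]), 0.05)

  # running: measured double float matches flight_fraction / cadence
  run <- simulate_recording(coh$running, subject_effect(seed = 4), 20)
  env <- foot_envelopes(run)
  g <- gait_phase_features(env$L, env$R, 100)
  expect_lt(abs(g[["double_float_s"]] - 0.10 / 1.4), 0.011)

  # windows with no full stance yield (0, 0)
  sit <- simulate_recording(coh$sitting, subject_effect(seed = 5), 20)
  env <- foot_envelopes(sit)
  expect_equal(unname(gait_phase_features(env$L, env$R, 100)), c(0, 0))
})

test_that("spectral features recover constructed spectral lines", {
  t <- (0:1999) / 100
  expect_equal(unname(frequency_features(rep(5, 2000), 100)), rep(0, 5))

  f1 <- frequency_features(sin(2 * pi * 3 * t), 100)
  expect_equal(f1[["wmean_1.67_10hz"]], 3.0, tolerance = 0.05 + 1e-9)

  f2 <- frequency_features(sin(2 * pi * 3 * t) + sin(2 * pi * 7 * t), 100)
  expect_equal(f2[["wmean_1.67_10hz"]], 5.0, tolerance = 0.05 + 1e-9)

  # AC band statistics see exactly the two lines
  expect_gt(f2[["ac_mean_2_10hz"]], 0)
  expect_gt(f2[["power_density"]], 0)
})

test_that("pressure-distribution features follow their sign conventions", {
  n <- 500
  chans <- matrix(0, n, 14, dimnames = list(NULL, channel_names()))
  wave <- 5 + 3 * sin(2 * pi * (1:n) / 100)

  # forefoot envelope identical to heel: difference 0, correlations 1
  for (ch in c("L1", "R1", "L5", "R5")) chans[, ch] <- wave
  d <- pressure_distribution_features(chans, c(1, 5))
  expect_equal(d[["ap_diff"]], 0)
  expect_equal(d[["ap_cor.L"]], 1)
  expect_equal(d[["ap_cor.R"]], 1)

  # heel loaded at 10 N, forefoot silent: difference is forefoot - heel
  chans2 <- matrix(0, n, 14, dimnames = list(NULL, channel_names()))
  chans2[, c("L1", "R1")] <- 10
  d2 <- pressure_distribution_features(chans2, c(1, 4, 5, 6, 7))
  expect_equal(d2[["ap_diff"]], -10)
  expect_equal(d2[["ap_cor.L"]], 0)  # zero-variance pair -> 0

  # identical medial and lateral forefoot series
  chans3 <- matrix(0, n, 14, dimnames = list(NULL, channel_names()))
  for (ch in c("L4", "L6", "R4", "R6")) chans3[, ch] <- wave
  d3 <- pressure_distribution_features(chans3, c(4, 6))
  expect_equal(d3[["ml_diff"]], 0)
  expect_equal(d3[["ml_cor.L"]], 1)
})

test_that("the assembled feature vector matches the catalog exactly", {
  rec <- simulate_recording(default_activity_profiles()$walking_flat,
                            subject_effect(seed = 9), 20)
  win <- rec$channels[1:2000, ]

  fv <- extract_features(win, sensor_config(1:7), 100)
  expect_length(fv, 167)
  expect_identical(names(fv), feature_catalog(1:7)$feature_id)
  expect_true(all(is.finite(fv)))

  fv1 <- extract_features(win, sensor_config(1), 100)
  expect_length(fv1, 29)

  zeros <- matrix(0, 2000, 14, dimnames = list(NULL, channel_names()))
  expect_true(all(extract_features(zeros, 1:7, 100) == 0))
})

test_that("scaling all channels scales magnitudes and fixes shape features", {
  rec <- simulate_recording(default_activity_profiles()$walking_flat,
                            subject_effect(seed = 10), 20)
  win <- rec$channels[1:2000, ]
  k <- 2.5
  f1 <- extract_features(win, 1:7, 100)
  f2 <- extract_features(k * win, 1:7, 100)

  ids <- feature_catalog(1:7)
  mag <- c(grep("^gs\\.", ids$feature_id, value = TRUE),
           grep("^pk\\.mag", ids$feature_id, value = TRUE),
           "dist.ap_diff", "dist.ml_diff", "gait.landing_lift_diff")
  expect_equal(f2[mag], k * f1[mag], tolerance = 1e-8)

  fixed <- c(grep("^pk\\.(n|interval|width)", ids$feature_id, value = TRUE),
             "freq.wmean_1.67_10hz", "gait.double_float_s",
             "dist.ap_cor.L", "dist.ap_cor.R", "dist.ml_cor.L", "dist.ml_cor.R")
  expect_equal(f2[fixed], f1[fixed], tolerance = 1e-8)
})

test_that("averaged features are invariant to which foot is called left", {
  rec <- simulate_recording(default_activity_profiles()$walking_flat,
                            subject_effect(seed = 12), 20)
  win <- rec$channels[1:2000, ]
  swapped <- win[, c(paste0("R", 1:7), paste0("L", 1:7))]
  colnames(swapped) <- channel_names()

  f1 <- extract_features(win, 1:7, 100)
  f2 <- extract_features(swapped, 1:7, 100)
  sym <- c("gait.landing_lift_diff", "gait.double_float_s",
           "dist.ap_diff", "dist.ml_diff",
           "freq.power_density", "freq.wmean_1.67_10hz")
  expect_equal(f2[sym], f1[sym], tolerance = 1e-9)
  # per-foot features swap rather than change
  expect_equal(f2[["dist.ap_cor.L"]], f1[["dist.ap_cor.R"]])
  expect_equal(f2[["gs.mean.L1"]], f1[["gs.mean.R1"]])
})
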