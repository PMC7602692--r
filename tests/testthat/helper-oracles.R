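# Independent reference implementations and signal constructors used by the
# tests. These deliberately avoid the package's own code paths.

# brute-force local-maxima detector with plateau midpoints (pure R, O(n^2))
brute_peaks <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1
      if (j < n && x[j + 1] < x[j]) {
        out <- c(out, (i + j) %/% 2)
        i <- j + 1
      } else {
        i <- max(j, i + 1)
      }
    } else {
      i <- i + 1
    }
  }
  out
}

# brute-force width at rel * height around peak index i (samples)
brute_width <- function(x, i, rel = 0.30) {
  thr <- rel * x[i]
  a <- i
  while (a > 1 && x[a - 1] >= thr) a <- a - 1
  b <- i
  while (b < length(x) && x[b + 1] >= thr) b <- b + 1
  b - a
}

# closed-form magnitude gain of an order-2 Butterworth low-pass applied
# forward and backward (zero-phase): |H|^2 with |H|^2 = 1 / (1 + (f/fc)^4)
butter2_zero_phase_gain <- function(f_hz, fc_hz = 5) {
  1 / (1 + (f_hz / fc_hz)^4)
}

# raised-cosine pulse train: one pulse of height `amp`, half-width `w` (s),
# centered at each element of `centers`
pulse_train <- function(t, centers, amp = 1, w = 0.4) {
  x <- numeric(length(t))
  for (c0 in centers) {
    d <- t - c0
    hit <- abs(d) <= w
    x[hit] <- x[hit] + amp * 0.5 * (1 + cos(pi * d[hit] / w))
  }
  x
}

# small all-activity cohort for pipeline tests (short bouts, quick)
tiny_cohort <- function(n_subjects = 5, duration_s = 60, seed = 42,
                        noise_sd = 0.1) {
  simulate_cohort(n_subjects,
                  profiles = default_activity_profiles(noise_sd = noise_sd),
                  durations = default_durations(duration_s, duration_s),
                  master_seed = seed)
}

# well-separated Gaussian clusters, one per class, for forest oracles
cluster_data <- function(n_per_class = 30, n_classes = 3, n_features = 5,
                         sep = 10, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    matrix(rnorm(n_per_class * n_features, mean = k * sep),
           n_per_class, n_features)
  }))
  colnames(x) <- paste0("f", seq_len(n_features))
  list(x = as.data.frame(x),
       y = rep(letters[seq_len(n_classes)], each = n_per_class))
}

zero_noise_profiles <- function() default_activity_profiles(noise_sd = 0)

foot_envelopes <- function(rec, sites = 1:7) {
  list(L = do.call(pmax, as.data.frame(rec$channels[, paste0("L", sites)])),
       R = do.call(pmax, as.data.frame(rec$channels[, paste0("R", sites)])))
}
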