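# Brute-force oracles and shared fixtures, independent of the package's
# implementation paths.

# centered truncated window indices, matching the documented convention
bf_window <- function(i, n, L) {
  hl <- (L - 1L) %/% 2L
  hr <- L - 1L - hl
  max(1L, i - hl):min(n, i + hr)
}

bf_moving_median <- function(x, L) {
  n <- length(x)
  vapply(seq_len(n), function(i) stats::median(x[bf_window(i, n, L)]),
         numeric(1))
}

bf_moving_sd_pop <- function(x, L) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[bf_window(i, n, L)]
    sqrt(mean((w - mean(w))^2))
  }, numeric(1))
}

# maximum-cardinality bipartite matching (Kuhn's augmenting paths) over an
# adjacency list: adj[[i]] = admissible right-side partners of left node i
bf_max_matching <- function(adj, n_right) {
  match_r <- integer(n_right)        # 0 = free
  seen <- logical(n_right)
  try_aug <- function(i) {
    for (j in adj[[i]]) {
      if (!seen[j]) {
        seen[j] <<- TRUE
        if (match_r[j] == 0L || try_aug(match_r[j])) {
          match_r[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_along(adj)) {
    seen[] <- FALSE
    if (try_aug(i)) size <- size + 1L
  }
  size
}

# minimal difc_peaks-shaped data frame from peak times
peaks_df <- function(times, probe = "P1", amplitude = 1, fs = 500) {
  n <- length(times)
  data.frame(probe = rep(probe, n),
             index = as.integer(round(times * fs)) + 1L,
             time_s = times, amplitude = rep(amplitude, length.out = n),
             local_noise = rep(0.1, n), snr_db = rep(20, n),
             prominence = rep(amplitude, length.out = n),
             width_s = rep(NA_real_, n))
}

# mouse-scale scan conditions (3.6 bright-cell transits/min) with speed
# distributions set explicitly so transit delays stay within the default
# matching bounds (6-600 mm/s over 3 mm)
mouse_scan_config <- function(seed, duration_s = 600,
                               event_rate_per_min = 3.6, noise_sd = 0.02,
                               amplitude_lognorm = c(log(0.5), 0.2), ...) {
  difc_sim_config(duration_s = duration_s, seed = seed,
                  event_rate_per_min = event_rate_per_min,
                  arterial_speed_mm_s = c(100, 25),
                  venous_speed_mm_s = c(20, 5),
                  amplitude_lognorm = amplitude_lognorm,
                  noise_sd = noise_sd, artifact_rate_per_min = 0, ...)
}

# control-recording conditions (no transits) and the pooled false-alarm
# rate of the full pipeline over three 1-hour scans; sub-seeds derive from
# one root seed
control_config <- function(seed, duration_s = 3600) {
  difc_sim_config(duration_s = duration_s, seed = seed,
                  event_rate_per_min = 0,
                  baseline_level = 1.0, drift_amp = 0.1,
                  drift_period_s = 300, noise_sd = 0.02,
                  artifact_rate_per_min = 1,
                  artifact_amplitude_lognorm = c(log(0.25), 0.25))
}

pooled_false_alarm_rate <- function(root_seed, n_scans = 3,
                                    duration_s = 3600) {
  seeds <- difcr:::derive_seeds(root_seed, paste0("scan", seq_len(n_scans)))
  cfg_pipe <- difc_pipeline_config(delay_bounds_s = c(0.01, 0.25))
  n_matched <- 0L
  for (s in seeds) {
    sim <- simulate_recording(control_config(s, duration_s))
    scan <- difc_process(sim$recording, cfg_pipe)
    n_matched <- n_matched + nrow(scan$matched)
  }
  n_matched / (n_scans * duration_s / 60)
}
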