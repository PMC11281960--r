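test_that("pulse waveform is a Gaussian parameterized by FWHM", {
  # zero amplitude annihilates
  expect_identical(pulse_waveform(0, 0.5, 0.02, 1000, 100), rep(0, 100))
  # peak value reached exactly when the center lies on a sample instant
  p <- pulse_waveform(1.0, 0.5, 0.02, 1000, 1000)
  expect_identical(p[501], 1.0)
  expect_true(all(p <= 1.0) && all(p >= 0))
  # half maximum at center +/- FWHM/2 (sample-aligned at 1000 Hz)
  expect_equal(p[501 + 10], 0.5, tolerance = 1e-9)
  expect_equal(p[501 - 10], 0.5, tolerance = 1e-9)
  expect_error(pulse_waveform(1, 0.5, 0, 1000, 100), "width")
  expect_error(pulse_waveform(1, 0.5, 0.02, -5, 100), "sampling")
})

test_that("background trace follows its closed form", {
  flat <- difc_sim_config(duration_s = 10, sampling_hz = 200,
                          baseline_level = 2.5, dye_background_amp = 0,
                          drift_amp = 0)
  expect_identical(background_trace(flat, 100), rep(2.5, 100))

  # half-life definition: at t = halflife the dye term has halved
  hl <- difc_sim_config(duration_s = 700, sampling_hz = 200,
                        baseline_level = 1, dye_background_amp = 4,
                        dye_clearance_halflife_s = 600, drift_amp = 0)
  bg <- background_trace(hl, 600 * 200 + 1)
  expect_equal(bg[600 * 200 + 1] - 1, 2.0, tolerance = 1e-12)

  # pointwise oracle re-evaluation of the full model
  cfg <- difc_sim_config(duration_s = 30, sampling_hz = 250,
                         baseline_level = 1.2, dye_background_amp = 3,
                         dye_clearance_halflife_s = 120, drift_amp = 0.4,
                         drift_period_s = 17)
  n <- 5000
  t <- (seq_len(n) - 1) / 250
  oracle <- 1.2 + 3 * 2^(-t / 120) + 0.4 * sin(2 * pi * t / 17)
  expect_equal(background_trace(cfg, n), oracle, tolerance = 1e-12)

  expect_error(difc_sim_config(baseline_level = -1), "baseline")
})

test_that("config invariants are enforced", {
  expect_error(difc_sim_config(sampling_hz = 100), "sampling_hz")
  expect_error(difc_sim_config(arterial_fraction = 1.5), "arterial_fraction")
  expect_error(difc_sim_config(event_rate_per_min = -1), "event_rate")
  expect_error(difc_sim_config(duration_s = 0), "duration")
  expect_error(difc_sim_config(min_speed_mm_s = 0), "min_speed")
})

test_that("a simulation with no stochastic terms equals its background", {
  cfg <- difc_sim_config(duration_s = 20, sampling_hz = 200, seed = 4,
                         event_rate_per_min = 0, artifact_rate_per_min = 0,
                         noise_sd = 0, drift_amp = 0, dye_background_amp = 0,
                         baseline_level = 1.5)
  sim <- simulate_recording(cfg)
  expect_identical(sim$recording$p1, rep(1.5, 4000))
  expect_identical(sim$recording$p2, rep(1.5, 4000))
  expect_identical(nrow(sim$truth$transits), 0L)
  expect_identical(nrow(sim$truth$artifacts), 0L)
})

test_that("a noiseless simulation is the deterministic sum of background and pulses", {
  cfg <- difc_sim_config(duration_s = 60, sampling_hz = 500, seed = 21,
                         event_rate_per_min = 8, artifact_rate_per_min = 0,
                         noise_sd = 0, drift_amp = 0.2, drift_period_s = 30)
  sim <- simulate_recording(cfg)
  tr <- sim$truth$transits
  expect_gt(nrow(tr), 0)
  n <- length(sim$recording$p1)
  manual_p1 <- background_trace(cfg, n)
  manual_p2 <- manual_p1
  for (i in seq_len(nrow(tr))) {
    manual_p1 <- manual_p1 +
      pulse_waveform(tr$amplitude[i], tr$t_p1[i], tr$width_s[i], 500, n)
    manual_p2 <- manual_p2 +
      pulse_waveform(tr$amplitude[i], tr$t_p2[i], tr$width_s[i], 500, n)
  }
  expect_equal(sim$recording$p1, manual_p1, tolerance = 1e-9)
  expect_equal(sim$recording$p2, manual_p2, tolerance = 1e-9)
})

test_that("identical configurations give bit-identical recordings and truth", {
  cfg <- difc_sim_config(duration_s = 30, seed = 99)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$p1, b$recording$p1)
  expect_identical(a$recording$p2, b$recording$p2)
  expect_identical(a$truth$transits, b$truth$transits)
  expect_identical(a$truth$artifacts, b$truth$artifacts)
})

test_that("RNG sub-streams isolate components from one another", {
  base <- difc_sim_config(duration_s = 60, seed = 5)
  alt_noise <- difc_sim_config(duration_s = 60, seed = 5, noise_sd = 0.1)
  alt_art <- difc_sim_config(duration_s = 60, seed = 5,
                             artifact_rate_per_min = 10)
  expect_identical(simulate_recording(base)$truth$transits,
                   simulate_recording(alt_noise)$truth$transits)
  expect_identical(simulate_recording(base)$truth$transits,
                   simulate_recording(alt_art)$truth$transits)
})

test_that("delay geometry and direction bookkeeping hold for every transit", {
  for (seed in c(2, 13, 77)) {
    cfg <- difc_sim_config(duration_s = 120, seed = seed,
                           event_rate_per_min = 20, noise_sd = 0)
    tr <- simulate_recording(cfg)$truth$transits
    expect_gt(nrow(tr), 0)
    delay <- abs(tr$t_p2 - tr$t_p1)
    expect_true(all(delay > 0))
    expect_equal(delay * tr$speed_mm_s, rep(3.0, nrow(tr)),
                 tolerance = 1e-9)
    expect_identical(tr$direction == "forward", tr$t_p1 < tr$t_p2)
    expect_true(all(tr$t_p1 >= 0 & tr$t_p1 <= 120))
    expect_true(all(tr$t_p2 >= 0 & tr$t_p2 <= 120))
    expect_equal(tr$width_s, cfg$fov_mm / tr$speed_mm_s, tolerance = 1e-12)
  }
})

test_that("venous transits are wider than arterial ones on average", {
  cfg <- difc_sim_config(duration_s = 600, seed = 8, event_rate_per_min = 30,
                         noise_sd = 0, arterial_speed_mm_s = c(100, 30),
                         venous_speed_mm_s = c(20, 8))
  tr <- simulate_recording(cfg)$truth$transits
  expect_gt(mean(tr$width_s[tr$direction == "reverse"]),
            mean(tr$width_s[tr$direction == "forward"]))
})

test_that("transit counts follow the configured Poisson law", {
  n_seeds <- 150
  lambda <- 3.6          # 1-minute scans at 3.6 transits/min
  counts <- vapply(seq_len(n_seeds), function(s) {
    cfg <- difc_sim_config(duration_s = 60, sampling_hz = 200, seed = s,
                           event_rate_per_min = lambda, noise_sd = 0,
                           artifact_rate_per_min = 0)
    nrow(simulate_recording(cfg)$truth$transits)
  }, integer(1))
  se <- sqrt(lambda / n_seeds)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # chi-square goodness of fit against Poisson(3.6), binned tails
  breaks <- c(-Inf, 1, 2, 3, 4, 5, 6, Inf)
  obs <- table(cut(counts, breaks))
  p <- diff(ppois(c(-Inf, 1, 2, 3, 4, 5, 6, Inf), lambda))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("ground truth survives a JSON round trip", {
  sim <- simulate_recording(difc_sim_config(duration_s = 60, seed = 31))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$transits, sim$truth$transits, tolerance = 1e-12)
  expect_equal(back$artifacts, sim$truth$artifacts, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$duration_s, 60)
})
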