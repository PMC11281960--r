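#' Simulation configuration for synthetic two-probe recordings
#'
#' Collects every knob of the synthetic DiFC recording generator.  Defaults
#' describe a typical scan of the mouse saphenous vessels: cells arrive
#' as a Poisson process at 3.6 transits per minute, the two probes are 3 mm
#' apart, pulse amplitudes are log-normal and well above the noise floor
#' (the "prelabeled" scenario), the background carries a slow sinusoidal
#' drift, and the additive Gaussian noise is band-limited to the
#' instrument's 100 Hz low-pass.
#'
#' @param duration_s scan length, seconds.
#' @param sampling_hz sampling rate, samples/second; must be at least 200
#'   (twice the 100 Hz analog band).
#' @param probe_separation_mm distance between probes P1 and P2 along the
#'   vessel, millimeters.
#' @param fov_mm effective probe field-of-view diameter, millimeters; sets
#'   pulse width as `fov_mm / speed`.
#' @param event_rate_per_min mean matched-cell transits per minute.
#' @param arterial_fraction proportion of transits in the forward
#'   (arterial, P1-before-P2) direction, in `[0, 1]`.
#' @param arterial_speed_mm_s,venous_speed_mm_s `(mean, sd)` of the
#'   truncated-normal speed distributions, mm/s.
#' @param min_speed_mm_s lower truncation for both speed distributions,
#'   mm/s (strictly positive).
#' @param amplitude_lognorm `(log-mean, log-sd)` of pulse amplitudes,
#'   signal units.
#' @param baseline_level constant background level, signal units.
#' @param dye_background_amp initial amplitude of the unbound-dye
#'   background component, signal units; it decays exponentially with
#'   half-life `dye_clearance_halflife_s`.
#' @param dye_clearance_halflife_s clearance half-life, seconds.
#' @param drift_amp,drift_period_s slow sinusoidal drift amplitude (signal
#'   units) and period (seconds).
#' @param noise_sd standard deviation of the additive Gaussian noise before
#'   band-limiting, signal units.
#' @param filter_noise logical; band-limit the noise with a zero-phase
#'   low-pass at `lowpass_hz` (mirrors the instrument's analog filter).
#' @param lowpass_hz noise band limit, Hz.
#' @param artifact_rate_per_min spurious single-probe pulses per minute per
#'   probe.
#' @param artifact_amplitude_lognorm `(log-mean, log-sd)` of artifact
#'   amplitudes.
#' @param seed integer root seed.  Independent sub-streams are derived for
#'   counts, times, speeds, amplitudes, noise and artifacts, so changing
#'   one component's parameters does not perturb the others' draws.
#'
#' @return An object of class `difc_sim_config` (a validated named list).
#' @seealso [simulate_recording()]
#' @export
difc_sim_config <- function(duration_s = 600,
                            sampling_hz = 500,
                            probe_separation_mm = 3.0,
                            fov_mm = 1.0,
                            event_rate_per_min = 3.6,
                            arterial_fraction = 0.5,
                            arterial_speed_mm_s = c(100, 30),
                            venous_speed_mm_s = c(20, 8),
                            min_speed_mm_s = 1,
                            amplitude_lognorm = c(log(0.5), 0.4),
                            baseline_level = 1.0,
                            dye_background_amp = 0,
                            dye_clearance_halflife_s = 3 * 3600,
                            drift_amp = 0.1,
                            drift_period_s = 300,
                            noise_sd = 0.02,
                            filter_noise = TRUE,
                            lowpass_hz = 100,
                            artifact_rate_per_min = 1,
                            artifact_amplitude_lognorm = c(log(0.25), 0.25),
                            seed = 1L) {
  .check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  .check_scalar(sampling_hz, "sampling_hz", lower = 200)
  .check_scalar(probe_separation_mm, "probe_separation_mm", lower = 0,
                strict_lower = TRUE)
  .check_scalar(fov_mm, "fov_mm", lower = 0, strict_lower = TRUE)
  .check_scalar(event_rate_per_min, "event_rate_per_min", lower = 0)
  .check_scalar(arterial_fraction, "arterial_fraction", lower = 0, upper = 1)
  .check_pair(arterial_speed_mm_s, "arterial_speed_mm_s")
  .check_pair(venous_speed_mm_s, "venous_speed_mm_s")
  .check_scalar(min_speed_mm_s, "min_speed_mm_s", lower = 0,
                strict_lower = TRUE)
  if (arterial_speed_mm_s[2] < 0 || venous_speed_mm_s[2] < 0)
    stop("speed sds must be >= 0", call. = FALSE)
  .check_pair(amplitude_lognorm, "amplitude_lognorm")
  .check_scalar(baseline_level, "baseline_level", lower = 0)
  .check_scalar(dye_background_amp, "dye_background_amp", lower = 0)
  .check_scalar(dye_clearance_halflife_s, "dye_clearance_halflife_s",
                lower = 0, strict_lower = TRUE)
  .check_scalar(drift_amp, "drift_amp", lower = 0)
  .check_scalar(drift_period_s, "drift_period_s", lower = 0,
                strict_lower = TRUE)
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  .check_scalar(lowpass_hz, "lowpass_hz", lower = 0, strict_lower = TRUE)
  .check_scalar(artifact_rate_per_min, "artifact_rate_per_min", lower = 0)
  .check_pair(artifact_amplitude_lognorm, "artifact_amplitude_lognorm")
  .check_scalar(seed, "seed")
  structure(list(duration_s = duration_s, sampling_hz = sampling_hz,
                 probe_separation_mm = probe_separation_mm, fov_mm = fov_mm,
                 event_rate_per_min = event_rate_per_min,
                 arterial_fraction = arterial_fraction,
                 arterial_speed_mm_s = arterial_speed_mm_s,
                 venous_speed_mm_s = venous_speed_mm_s,
                 min_speed_mm_s = min_speed_mm_s,
                 amplitude_lognorm = amplitude_lognorm,
                 baseline_level = baseline_level,
                 dye_background_amp = dye_background_amp,
                 dye_clearance_halflife_s = dye_clearance_halflife_s,
                 drift_amp = drift_amp, drift_period_s = drift_period_s,
                 noise_sd = noise_sd, filter_noise = isTRUE(filter_noise),
                 lowpass_hz = lowpass_hz,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_amplitude_lognorm = artifact_amplitude_lognorm,
                 seed = seed),
            class = "difc_sim_config")
}

#' @export
print.difc_sim_config <- function(x, ...) {
  cat(sprintf("<difc_sim_config> %.0f s @ %g Hz, %.2g transits/min, %.2g artifacts/min/probe, seed %d\n",
              x$duration_s, x$sampling_hz, x$event_rate_per_min,
              x$artifact_rate_per_min, as.integer(x$seed)))
  invisible(x)
}

#' Gaussian transit pulse sampled on a uniform grid
#'
#' A cell transit through a probe's field of view is modeled as a Gaussian
#' pulse in time, parameterized by its full width at half maximum:
#' `A * exp(-(t - center)^2 / (2 * sigma^2))` with
#' `sigma = width_s / (2 * sqrt(2 * log(2)))`.
#'
#' @param amplitude peak amplitude, signal units (>= 0).
#' @param center_s pulse center, seconds.
#' @param width_s full width at half maximum, seconds (> 0).
#' @param sampling_hz sampling rate, samples/second.
#' @param n_samples length of the returned vector.
#' @return Numeric vector of `n_samples` non-negative values; sample `i`
#'   corresponds to time `(i - 1) / sampling_hz`.
#' @examples
#' p <- pulse_waveform(1, 0.5, 0.02, 1000, 1000)
#' max(p)
#' @export
pulse_waveform <- function(amplitude, center_s, width_s, sampling_hz,
                           n_samples) {
  .check_scalar(amplitude, "amplitude", lower = 0)
  .check_scalar(center_s, "center_s")
  .check_scalar(width_s, "width_s", lower = 0, strict_lower = TRUE)
  .check_scalar(sampling_hz, "sampling_hz", lower = 0, strict_lower = TRUE)
  .check_scalar(n_samples, "n_samples", lower = 1)
  t <- (seq_len(n_samples) - 1) / sampling_hz
  sigma <- width_s / (2 * sqrt(2 * log(2)))
  amplitude * exp(-(t - center_s)^2 / (2 * sigma^2))
}

#' Deterministic background trace
#'
#' The slowly varying background is a constant baseline plus an
#' exponentially clearing unbound-dye component (half-life form) plus a
#' slow sinusoidal drift:
#' `baseline + dye_amp * 2^(-t / halflife) + drift_amp * sin(2 pi t / period)`.
#'
#' @param config a [difc_sim_config()].
#' @param n_samples number of samples to generate.
#' @return Numeric vector of length `n_samples`.
#' @export
background_trace <- function(config, n_samples) {
  stopifnot(inherits(config, "difc_sim_config"))
  .check_scalar(n_samples, "n_samples", lower = 1)
  t <- (seq_len(n_samples) - 1) / config$sampling_hz
  bg <- rep(config$baseline_level, n_samples)
  if (config$dye_background_amp > 0)
    bg <- bg + config$dye_background_amp *
      2^(-t / config$dye_clearance_halflife_s)
  if (config$drift_amp > 0)
    bg <- bg + config$drift_amp * sin(2 * pi * t / config$drift_period_s)
  bg
}

# truncated-normal speeds via inverse-CDF (deterministic draw count)
.rspeed <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(max(mean, lower), n))
  plo <- pnorm((lower - mean) / sd)
  u <- runif(n, plo, 1)
  mean + sd * qnorm(pmin(u, 1 - 1e-16))
}

# add a Gaussian pulse in place, truncated at +/- 8 sigma
.add_pulse <- function(x, amplitude, center_s, width_s, fs) {
  sigma <- width_s / (2 * sqrt(2 * log(2)))
  n <- length(x)
  i0 <- max(1L, floor((center_s - 8 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((center_s + 8 * sigma) * fs) + 1L)
  if (i0 > i1) return(x)
  idx <- i0:i1
  t <- (idx - 1) / fs
  x[idx] <- x[idx] + amplitude * exp(-(t - center_s)^2 / (2 * sigma^2))
  x
}

.lowpass_noise <- function(noise, fs, cutoff_hz) {
  w <- cutoff_hz / (fs / 2)
  if (w >= 1) return(noise)
  bf <- signal::butter(4, w, type = "low")
  as.numeric(signal::filtfilt(bf, noise))
}

#' Simulate a ground-truthed two-probe DiFC recording
#'
#' Draws a Poisson number of cell transits, assigns each a flow direction
#' (forward/arterial: seen at P1 then P2; reverse/venous: P2 then P1), a
#' truncated-normal speed, a log-normal amplitude and a Gaussian pulse of
#' width `fov_mm / speed`, with inter-probe delay
#' `probe_separation_mm / speed`.  Spurious single-probe artifact pulses are
#' placed independently on each probe.  Each channel is the background
#' trace plus its pulses plus (optionally band-limited) Gaussian noise.
#' Identical configurations, including the seed, give bit-identical output.
#'
#' @param config a [difc_sim_config()].
#' @return A list with elements `recording` (a [difc_recording()]) and
#'   `truth` (class `difc_truth`: data frames `transits` with columns
#'   `t_p1`, `t_p2`, `direction`, `speed_mm_s`, `amplitude`, `width_s`, and
#'   `artifacts` with columns `probe`, `time_s`, `amplitude`, `width_s`).
#' @examples
#' sim <- simulate_recording(difc_sim_config(duration_s = 30, seed = 7))
#' sim$recording
#' nrow(sim$truth$transits)
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "difc_sim_config"))
  fs <- config$sampling_hz
  dur <- config$duration_s
  n <- as.integer(round(dur * fs))
  if (n < 1) stop("duration too short for sampling rate", call. = FALSE)
  seeds <- derive_seeds(config$seed,
                        c("counts", "times", "speeds", "amplitudes",
                          "noise", "artifacts"))

  n_ev <- with_seed(seeds[["counts"]],
                    rpois(1L, config$event_rate_per_min * dur / 60))

  dir_fwd <- logical(0); speed <- numeric(0)
  if (n_ev > 0) {
    sp <- with_seed(seeds[["speeds"]], {
      fwd <- runif(n_ev) < config$arterial_fraction
      s <- numeric(n_ev)
      s[fwd] <- .rspeed(sum(fwd), config$arterial_speed_mm_s[1],
                        config$arterial_speed_mm_s[2], config$min_speed_mm_s)
      s[!fwd] <- .rspeed(sum(!fwd), config$venous_speed_mm_s[1],
                         config$venous_speed_mm_s[2], config$min_speed_mm_s)
      list(fwd = fwd, s = s)
    })
    dir_fwd <- sp$fwd; speed <- sp$s
  }
  delay <- config$probe_separation_mm / speed
  width <- config$fov_mm / speed

  # first-probe arrival uniform in [0, duration - delay] so both pulse
  # centers stay inside the record
  t_first <- if (n_ev > 0)
    with_seed(seeds[["times"]], runif(n_ev) * pmax(0, dur - delay))
  else numeric(0)
  t_p1 <- ifelse(dir_fwd, t_first, t_first + delay)
  t_p2 <- ifelse(dir_fwd, t_first + delay, t_first)

  amp <- if (n_ev > 0)
    with_seed(seeds[["amplitudes"]],
              rlnorm(n_ev, config$amplitude_lognorm[1],
                     config$amplitude_lognorm[2]))
  else numeric(0)

  arts <- with_seed(seeds[["artifacts"]], {
    per_probe <- lapply(c("P1", "P2"), function(pr) {
      m <- rpois(1L, config$artifact_rate_per_min * dur / 60)
      if (m == 0)
        return(data.frame(probe = character(0), time_s = numeric(0),
                          amplitude = numeric(0), width_s = numeric(0)))
      tm <- runif(m, 0, dur)
      a <- rlnorm(m, config$artifact_amplitude_lognorm[1],
                  config$artifact_amplitude_lognorm[2])
      fwd <- runif(m) < config$arterial_fraction
      s <- numeric(m)
      s[fwd] <- .rspeed(sum(fwd), config$arterial_speed_mm_s[1],
                        config$arterial_speed_mm_s[2], config$min_speed_mm_s)
      s[!fwd] <- .rspeed(sum(!fwd), config$venous_speed_mm_s[1],
                         config$venous_speed_mm_s[2], config$min_speed_mm_s)
      data.frame(probe = pr, time_s = tm, amplitude = a,
                 width_s = config$fov_mm / s)
    })
    do.call(rbind, per_probe)
  })

  bg <- background_trace(config, n)
  p1 <- bg; p2 <- bg
  if (n_ev > 0) {
    ord <- order(t_first)
    for (i in ord) {
      p1 <- .add_pulse(p1, amp[i], t_p1[i], width[i], fs)
      p2 <- .add_pulse(p2, amp[i], t_p2[i], width[i], fs)
    }
  }
  if (nrow(arts) > 0) {
    for (i in seq_len(nrow(arts))) {
      if (arts$probe[i] == "P1")
        p1 <- .add_pulse(p1, arts$amplitude[i], arts$time_s[i],
                         arts$width_s[i], fs)
      else
        p2 <- .add_pulse(p2, arts$amplitude[i], arts$time_s[i],
                         arts$width_s[i], fs)
    }
  }
  if (config$noise_sd > 0) {
    nz <- with_seed(seeds[["noise"]], {
      n1 <- rnorm(n, 0, config$noise_sd)
      n2 <- rnorm(n, 0, config$noise_sd)
      list(n1 = n1, n2 = n2)
    })
    if (config$filter_noise) {
      nz$n1 <- .lowpass_noise(nz$n1, fs, config$lowpass_hz)
      nz$n2 <- .lowpass_noise(nz$n2, fs, config$lowpass_hz)
    }
    p1 <- p1 + nz$n1
    p2 <- p2 + nz$n2
  }

  ord <- if (n_ev > 0) order(t_first) else integer(0)
  transits <- data.frame(t_p1 = t_p1[ord], t_p2 = t_p2[ord],
                         direction = ifelse(dir_fwd[ord], "forward",
                                            "reverse"),
                         speed_mm_s = speed[ord], amplitude = amp[ord],
                         width_s = width[ord])
  arts <- arts[order(arts$time_s), , drop = FALSE]
  rownames(arts) <- NULL
  truth <- structure(list(transits = transits,
                          artifacts = arts,
                          duration_s = dur),
                     class = "difc_truth")
  rec <- difc_recording(fs, p1, p2, units = "a.u.",
                        meta = list(seed = as.integer(config$seed),
                                    duration_s = dur,
                                    generator = "difcr::simulate_recording"))
  list(recording = rec, truth = truth)
}

#' @export
print.difc_truth <- function(x, ...) {
  cat(sprintf("<difc_truth> %d transits (%d forward / %d reverse), %d artifacts over %.0f s\n",
              nrow(x$transits), sum(x$transits$direction == "forward"),
              sum(x$transits$direction == "reverse"), nrow(x$artifacts),
              x$duration_s))
  invisible(x)
}

#' Write ground truth to a JSON sidecar
#' @param truth a `difc_truth` object from [simulate_recording()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "difc_truth"))
  jsonlite::write_json(list(duration_s = truth$duration_s,
                            transits = truth$transits,
                            artifacts = truth$artifacts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path path written by [write_truth()].
#' @return A `difc_truth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- as.data.frame(x$transits)
  ar <- as.data.frame(x$artifacts)
  if (nrow(tr) == 0)
    tr <- data.frame(t_p1 = numeric(0), t_p2 = numeric(0),
                     direction = character(0), speed_mm_s = numeric(0),
                     amplitude = numeric(0), width_s = numeric(0))
  if (nrow(ar) == 0)
    ar <- data.frame(probe = character(0), time_s = numeric(0),
                     amplitude = numeric(0), width_s = numeric(0))
  structure(list(transits = tr, artifacts = ar,
                 duration_s = x$duration_s),
            class = "difc_truth")
}
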