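#' Processing configuration
#'
#' Parameters of the enumeration pipeline.  The defaults are the published
#' operating point of the instrument's analysis: a 5 s moving-median
#' background window, a 1-min moving noise window, a detection threshold of
#' four times the local noise (12.04 dB), and 3 mm probe separation.
#'
#' @param background_window_s moving-median background window, seconds.
#' @param noise_window_s moving-sd noise window, seconds.
#' @param k detection threshold multiplier.
#' @param min_separation_s minimum spacing between retained peaks, seconds.
#' @param delay_bounds_s admissible matching delays `(min, max)`, seconds;
#'   the default `(0.005, 0.5)` spans 6-600 mm/s over 3 mm.
#' @param probe_separation_mm probe separation, millimeters.
#' @param robust_noise logical; use the MAD noise estimator
#'   (see [moving_noise()]).
#' @param require_prominence logical; require peak prominence to exceed
#'   `k` times the local noise as well (see [find_peak_candidates()]).
#' @param measure_widths logical; measure peak FWHMs.
#' @param fc_to_difc_scalar calibration scalar mapping flow-cytometry
#'   brightness units onto DiFC signal units (instrument-specific;
#'   default 1).
#' @return An object of class `difc_pipeline_config`.
#' @export
difc_pipeline_config <- function(background_window_s = 5,
                                 noise_window_s = 60,
                                 k = 4,
                                 min_separation_s = 0.02,
                                 delay_bounds_s = c(0.005, 0.5),
                                 probe_separation_mm = 3.0,
                                 robust_noise = FALSE,
                                 require_prominence = TRUE,
                                 measure_widths = TRUE,
                                 fc_to_difc_scalar = 1.0) {
  .check_scalar(background_window_s, "background_window_s", lower = 0,
                strict_lower = TRUE)
  .check_scalar(noise_window_s, "noise_window_s", lower = 0,
                strict_lower = TRUE)
  .check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  .check_scalar(min_separation_s, "min_separation_s", lower = 0)
  .check_pair(delay_bounds_s, "delay_bounds_s")
  if (delay_bounds_s[1] <= 0 || delay_bounds_s[1] >= delay_bounds_s[2])
    stop("delay bounds must satisfy 0 < min < max", call. = FALSE)
  .check_scalar(probe_separation_mm, "probe_separation_mm", lower = 0,
                strict_lower = TRUE)
  .check_scalar(fc_to_difc_scalar, "fc_to_difc_scalar", lower = 0,
                strict_lower = TRUE)
  structure(list(background_window_s = background_window_s,
                 noise_window_s = noise_window_s, k = k,
                 min_separation_s = min_separation_s,
                 delay_bounds_s = delay_bounds_s,
                 probe_separation_mm = probe_separation_mm,
                 robust_noise = isTRUE(robust_noise),
                 require_prominence = isTRUE(require_prominence),
                 measure_widths = isTRUE(measure_widths),
                 fc_to_difc_scalar = fc_to_difc_scalar),
            class = "difc_pipeline_config")
}

#' @export
print.difc_pipeline_config <- function(x, ...) {
  cat(sprintf("<difc_pipeline_config> bg %g s | noise %g s | k = %g | delays %g-%g s | sep %g mm\n",
              x$background_window_s, x$noise_window_s, x$k,
              x$delay_bounds_s[1], x$delay_bounds_s[2],
              x$probe_separation_mm))
  invisible(x)
}

#' Read configurations from JSON
#'
#' JSON keys map one-to-one onto the arguments of [difc_pipeline_config()]
#' / [difc_sim_config()]; missing keys take the defaults, unknown keys are
#' an error.
#'
#' @param path JSON file path.
#' @return A `difc_pipeline_config` / `difc_sim_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  .apply_config(x, difc_pipeline_config, path)
}

#' @rdname read_pipeline_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  .apply_config(x, difc_sim_config, path)
}

.apply_config <- function(x, ctor, path) {
  if (!is.list(x)) stop("config must be a JSON object: ", path,
                        call. = FALSE)
  unknown <- setdiff(names(x), names(formals(ctor)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  x <- lapply(x, function(v) if (is.integer(v)) as.numeric(v) else v)
  do.call(ctor, x)
}

#' Run the full enumeration pipeline on a recording
#'
#' Composes the published analysis steps on each probe channel: (1) the
#' background is estimated as the local moving median in a 5 s window and
#' subtracted; (2) the local noise (standard deviation) is computed in a
#' 1-min moving window; (3) peak candidates are local maxima exceeding
#' four times the local noise; finally P1/P2 candidates are matched by
#' inter-probe delay into directional cell detections, and unmatched peaks
#' are discarded from the cell count.
#'
#' @param recording a [difc_recording()].
#' @param config a [difc_pipeline_config()].
#' @param verbose logical; log per-stage counts.
#' @return An object of class `difc_scan`: list with `matched` (see
#'   [match_peaks()]), `unmatched_p1`, `unmatched_p2`, `peaks_p1`,
#'   `peaks_p2`, `noise_p1`, `noise_p2` (noise traces), `background_p1`,
#'   `background_p2`, `subtracted_p1`, `subtracted_p2`, `duration_min`,
#'   `count_rate_per_min` and `config`.
#' @examples
#' sim <- simulate_recording(difc_sim_config(duration_s = 60, seed = 11))
#' scan <- difc_process(sim$recording)
#' scan
#' @export
difc_process <- function(recording, config = difc_pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(recording, "difc_recording"),
            inherits(config, "difc_pipeline_config"))
  fs <- recording$sampling_hz
  chan <- lapply(c(p1 = "p1", p2 = "p2"), function(p) {
    x <- recording[[p]]
    bg <- moving_median_background(x, fs, config$background_window_s)
    sub <- subtract_background(x, bg)
    nt <- moving_noise(sub, fs, config$noise_window_s,
                       robust = config$robust_noise)
    pk <- find_peak_candidates(sub, nt, fs, k = config$k,
                               min_separation_s = config$min_separation_s,
                               probe = toupper(p),
                               require_prominence = config$require_prominence,
                               measure_widths = config$measure_widths)
    list(bg = bg, sub = sub, noise = nt, peaks = pk)
  })
  mt <- match_peaks(chan$p1$peaks, chan$p2$peaks,
                    delay_bounds_s = config$delay_bounds_s,
                    probe_separation_mm = config$probe_separation_mm)
  duration_min <- recording_duration_s(recording) / 60
  if (verbose)
    message(sprintf("peaks P1: %d, P2: %d | matched: %d | unmatched P1: %d, P2: %d | %.3g cells/min",
                    nrow(chan$p1$peaks), nrow(chan$p2$peaks),
                    nrow(mt$matched), mt$unmatched_p1, mt$unmatched_p2,
                    nrow(mt$matched) / duration_min))
  structure(list(matched = mt$matched,
                 unmatched_p1 = mt$unmatched_p1,
                 unmatched_p2 = mt$unmatched_p2,
                 peaks_p1 = chan$p1$peaks, peaks_p2 = chan$p2$peaks,
                 noise_p1 = chan$p1$noise, noise_p2 = chan$p2$noise,
                 background_p1 = chan$p1$bg, background_p2 = chan$p2$bg,
                 subtracted_p1 = chan$p1$sub, subtracted_p2 = chan$p2$sub,
                 sampling_hz = fs,
                 duration_min = duration_min,
                 count_rate_per_min = nrow(mt$matched) / duration_min,
                 config = config),
            class = "difc_scan")
}

#' @export
print.difc_scan <- function(x, ...) {
  m <- x$matched
  cat(sprintf("<difc_scan> %.1f min @ %g Hz\n", x$duration_min,
              x$sampling_hz))
  cat(sprintf("  peaks: %d (P1) + %d (P2); matched detections: %d (%d forward / %d reverse)\n",
              nrow(x$peaks_p1), nrow(x$peaks_p2), nrow(m),
              sum(m$direction == "forward"), sum(m$direction == "reverse")))
  cat(sprintf("  unmatched (discarded): %d (P1) + %d (P2)\n",
              x$unmatched_p1, x$unmatched_p2))
  cat(sprintf("  count rate: %.3g cells/min\n", x$count_rate_per_min))
  invisible(x)
}

#' @export
summary.difc_scan <- function(object, ...) {
  m <- object$matched
  out <- list(duration_min = object$duration_min,
              n_matched = nrow(m),
              count_rate_per_min = object$count_rate_per_min,
              n_forward = sum(m$direction == "forward"),
              n_reverse = sum(m$direction == "reverse"),
              unmatched_p1 = object$unmatched_p1,
              unmatched_p2 = object$unmatched_p2,
              mean_noise_p1 = mean(object$noise_p1$sigma),
              mean_noise_p2 = mean(object$noise_p2$sigma),
              mean_amplitude = if (nrow(m))
                mean(c(m$amplitude_p1, m$amplitude_p2)) else NA_real_,
              mean_speed_mm_s = if (nrow(m)) mean(m$speed_mm_s)
                else NA_real_,
              median_snr_db = if (nrow(m))
                median(c(m$snr_db_p1, m$snr_db_p2)) else NA_real_)
  class(out) <- "summary.difc_scan"
  out
}

#' @export
print.summary.difc_scan <- function(x, ...) {
  cat(sprintf("DiFC scan summary (%.1f min)\n", x$duration_min))
  cat(sprintf("  matched detections : %d (%.3g / min)\n", x$n_matched,
              x$count_rate_per_min))
  cat(sprintf("  direction          : %d forward (arterial), %d reverse (venous)\n",
              x$n_forward, x$n_reverse))
  cat(sprintf("  unmatched discarded: %d (P1), %d (P2)\n",
              x$unmatched_p1, x$unmatched_p2))
  cat(sprintf("  mean local noise   : %.4g (P1), %.4g (P2)\n",
              x$mean_noise_p1, x$mean_noise_p2))
  if (x$n_matched) {
    cat(sprintf("  mean peak amplitude: %.4g\n", x$mean_amplitude))
    cat(sprintf("  mean speed         : %.4g mm/s\n", x$mean_speed_mm_s))
    cat(sprintf("  median SNR         : %.4g dB\n", x$median_snr_db))
  }
  invisible(x)
}

#' @export
plot.difc_scan <- function(x, window_s = NULL, ...) {
  fs <- x$sampling_hz
  n <- length(x$subtracted_p1)
  idx <- if (is.null(window_s)) seq_len(n)
         else seq_len(min(n, round(window_s * fs)))
  t <- (idx - 1) / fs
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  for (p in c("p1", "p2")) {
    sub <- x[[paste0("subtracted_", p)]][idx]
    sig <- x[[paste0("noise_", p)]]$sigma[idx]
    plot(t, sub, type = "l", xlab = "time (s)",
         ylab = sprintf("%s - background", toupper(p)), ...)
    lines(t, x$config$k * sig, col = "red", lty = 2)
    pk <- x[[paste0("peaks_", p)]]
    pk <- pk[pk$time_s <= max(t), , drop = FALSE]
    if (nrow(pk)) points(pk$time_s, pk$amplitude, col = "blue", pch = 17)
    m <- x$matched
    tp <- if (p == "p1") m$t_p1 else m$t_p2
    keep <- tp <= max(t)
    if (any(keep))
      points(tp[keep],
             (if (p == "p1") m$amplitude_p1 else m$amplitude_p2)[keep],
             col = ifelse(m$direction[keep] == "forward", "red", "blue"),
             pch = 1, cex = 2)
  }
  invisible(x)
}

#' Serialize a scan result
#'
#' `write_scan_json()` writes a summary (counts, rate, parameters);
#' `write_detections_csv()` writes one row per matched detection.
#'
#' @param scan a `difc_scan`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_scan_json <- function(scan, path) {
  stopifnot(inherits(scan, "difc_scan"))
  s <- summary(scan)
  jsonlite::write_json(list(summary = unclass(s),
                            config = unclass(scan$config),
                            matched = scan$matched),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_scan_json
#' @export
write_detections_csv <- function(scan, path) {
  stopifnot(inherits(scan, "difc_scan"))
  write.csv(scan$matched, path, row.names = FALSE)
  invisible(path)
}
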