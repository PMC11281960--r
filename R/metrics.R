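#' Cell count rate
#'
#' @param n_matched number of matched detections.
#' @param duration_min scan duration, minutes (> 0).
#' @return Detections per minute.
#' @examples
#' count_rate(216, 60)  # 3.6 / min
#' @export
count_rate <- function(n_matched, duration_min) {
  .check_scalar(n_matched, "n_matched", lower = 0)
  .check_scalar(duration_min, "duration_min", lower = 0,
                strict_lower = TRUE)
  n_matched / duration_min
}

#' Effective blood sampling rate
#'
#' The volume of blood interrogated per unit time, estimated as the count
#' rate divided by the independently measured cell concentration:
#' `rate [cells/min] / concentration [cells/mL] * 1000 [uL/mL]`.
#'
#' @param count_rate_per_min matched-cell count rate, per minute.
#' @param concentration_per_ml cell concentration, cells/mL (> 0).
#' @return Sampling rate in microliters per minute.
#' @examples
#' blood_sampling_rate(3.6, 60)  # 60 uL/min
#' @export
blood_sampling_rate <- function(count_rate_per_min, concentration_per_ml) {
  .check_scalar(count_rate_per_min, "count_rate_per_min", lower = 0)
  .check_scalar(concentration_per_ml, "concentration_per_ml", lower = 0,
                strict_lower = TRUE)
  count_rate_per_min / concentration_per_ml * 1000
}

#' Projected clinical CTC counts
#'
#' Expected number of counted cells in a scan:
#' `concentration [cells/mL] x flow [mL/min] x scan [min] x sensitivity`.
#' For example, 10 CTCs/mL at a 100 mL/min wrist blood flow over a 10 min
#' scan with 30% labeling sensitivity projects 300 counts.
#'
#' @param concentration_per_ml cell concentration, cells/mL.
#' @param flow_ml_min interrogated blood flow, mL/min.
#' @param scan_min scan duration, minutes.
#' @param sensitivity detectable fraction, in `[0, 1]`.
#' @return Expected counts.
#' @examples
#' projected_counts(10, 100, 10, 0.30)  # 300
#' @export
projected_counts <- function(concentration_per_ml, flow_ml_min, scan_min,
                             sensitivity) {
  .check_scalar(concentration_per_ml, "concentration_per_ml", lower = 0)
  .check_scalar(flow_ml_min, "flow_ml_min", lower = 0)
  .check_scalar(scan_min, "scan_min", lower = 0)
  .check_scalar(sensitivity, "sensitivity", lower = 0, upper = 1)
  concentration_per_ml * flow_ml_min * scan_min * sensitivity
}

#' Fraction of a brightness distribution above a detection threshold
#'
#' The detectable fraction ("sensitivity") of a labeled cell population is
#' the proportion of its brightness distribution strictly above the
#' instrument's detection threshold.  Supply either an empirical sample of
#' brightness values or log-normal parameters, in which case the
#' closed-form upper tail `P(X > threshold)` is returned.
#'
#' @param threshold detection threshold, signal units (> 0).
#' @param brightness numeric sample of brightness values (empirical mode).
#' @param meanlog,sdlog log-normal parameters (parametric mode).
#' @return Proportion in `[0, 1]`.
#' @examples
#' detectable_fraction(1, meanlog = 0, sdlog = 1)  # 0.5
#' @export
detectable_fraction <- function(threshold, brightness = NULL,
                                meanlog = NULL, sdlog = NULL) {
  .check_scalar(threshold, "threshold", lower = 0, strict_lower = TRUE)
  if (!is.null(brightness)) {
    .check_numeric(brightness, "brightness")
    return(mean(brightness > threshold))
  }
  if (is.null(meanlog) || is.null(sdlog))
    stop("supply either `brightness` or both `meanlog` and `sdlog`",
         call. = FALSE)
  .check_scalar(meanlog, "meanlog")
  .check_scalar(sdlog, "sdlog", lower = 0, strict_lower = TRUE)
  plnorm(threshold, meanlog, sdlog, lower.tail = FALSE)
}

#' Ratio of mean local noise between two recordings
#'
#' Compares the noise floor of two processed recordings (for instance an
#' unbound-dye-elevated scan against an uninjected baseline) as the ratio
#' of their mean local-noise values.
#'
#' @param noise_condition,noise_baseline [moving_noise()] traces, numeric
#'   noise vectors, or scalar summaries.
#' @return Dimensionless ratio (condition / baseline).
#' @export
noise_ratio <- function(noise_condition, noise_baseline) {
  val <- function(x) {
    if (inherits(x, "difc_noise_trace")) mean(x$sigma)
    else if (is.numeric(x)) mean(x)
    else stop("unsupported noise summary", call. = FALSE)
  }
  a <- val(noise_condition); b <- val(noise_baseline)
  if (!is.finite(b) || b <= 0)
    stop("baseline noise summary must be > 0", call. = FALSE)
  a / b
}

#' Assemble the enumeration summary of a processed scan
#'
#' Combines a processed recording with an optional control recording (for
#' the operating false-alarm rate), an optional independently measured
#' cell concentration (for the blood sampling rate) and an optional
#' brightness distribution plus threshold (for the detectable fraction).
#'
#' @param scan a `difc_scan` from [difc_process()].
#' @param control_scan optional `difc_scan` of a control (no-cell)
#'   recording; its count rate is the false-alarm rate.
#' @param concentration_per_ml optional cell concentration, cells/mL.
#' @param brightness optional brightness sample (flow-cytometry units;
#'   multiplied by the pipeline's `fc_to_difc_scalar` calibration before
#'   thresholding).
#' @param threshold optional detection threshold in DiFC signal units;
#'   defaults to `k` times the scan's mean local noise.
#' @return An object of class `difc_summary` with fields
#'   `count_rate_per_min`, `false_alarm_rate_per_min`,
#'   `sampling_rate_ul_min`, `detectable_fraction`, `noise_ratio`.
#' @export
enumeration_summary <- function(scan, control_scan = NULL,
                                concentration_per_ml = NULL,
                                brightness = NULL, threshold = NULL) {
  stopifnot(inherits(scan, "difc_scan"))
  far <- if (!is.null(control_scan)) {
    stopifnot(inherits(control_scan, "difc_scan"))
    control_scan$count_rate_per_min
  } else NA_real_
  srate <- if (!is.null(concentration_per_ml))
    blood_sampling_rate(scan$count_rate_per_min, concentration_per_ml)
  else NA_real_
  dfrac <- if (!is.null(brightness)) {
    th <- if (!is.null(threshold)) threshold
    else scan$config$k * mean(c(scan$noise_p1$sigma, scan$noise_p2$sigma))
    detectable_fraction(th,
                        brightness = brightness *
                          scan$config$fc_to_difc_scalar)
  } else NA_real_
  nr <- if (!is.null(control_scan))
    noise_ratio(c(scan$noise_p1$sigma, scan$noise_p2$sigma),
                c(control_scan$noise_p1$sigma, control_scan$noise_p2$sigma))
  else NA_real_
  structure(list(count_rate_per_min = scan$count_rate_per_min,
                 false_alarm_rate_per_min = far,
                 sampling_rate_ul_min = srate,
                 detectable_fraction = dfrac,
                 noise_ratio = nr),
            class = "difc_summary")
}

#' @export
print.difc_summary <- function(x, ...) {
  fmt <- function(v, u) if (is.na(v)) "-" else sprintf("%.3g %s", v, u)
  cat("DiFC enumeration summary\n")
  cat("  count rate        :", fmt(x$count_rate_per_min, "cells/min"), "\n")
  cat("  false-alarm rate  :", fmt(x$false_alarm_rate_per_min,
                                   "cells/min"), "\n")
  cat("  blood sampling    :", fmt(x$sampling_rate_ul_min, "uL/min"), "\n")
  cat("  detectable fract. :", fmt(x$detectable_fraction, ""), "\n")
  cat("  noise ratio       :", fmt(x$noise_ratio, "x baseline"), "\n")
  invisible(x)
}

#' @rdname enumeration_summary
#' @param summary a `difc_summary`.
#' @param path output path.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "difc_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
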