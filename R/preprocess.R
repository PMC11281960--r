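#' Moving-median background estimate
#'
#' The signal background (tissue autofluorescence plus instrument offset,
#' and any slowly clearing unbound dye) is estimated as the local moving
#' median in a window of `window_s` seconds (default 5 s).  Windows are
#' centered on each sample and truncated (shrink) at the record edges; the
#' window length in samples is `round(window_s * sampling_hz)`, minimum 1,
#' and an even-length window's median is the mean of the central pair.
#' Because rare-cell pulses occupy far less than half of any window, the
#' median passes through them untouched.
#'
#' @param signal numeric sample vector.
#' @param sampling_hz sampling rate, samples/second.
#' @param window_s window length, seconds (> 0).
#' @return Numeric vector of the same length as `signal`.
#' @examples
#' x <- c(rep(2, 100), rep(2, 100) + dnorm(1:100, 50, 5))
#' bg <- moving_median_background(x, 100, window_s = 1)
#' @export
moving_median_background <- function(signal, sampling_hz, window_s = 5) {
  .check_numeric(signal, "signal")
  .check_scalar(sampling_hz, "sampling_hz", lower = 0, strict_lower = TRUE)
  .check_scalar(window_s, "window_s", lower = 0, strict_lower = TRUE)
  L <- max(1L, as.integer(round(window_s * sampling_hz)))
  .roll_median_trunc(as.numeric(signal), L)
}

#' Subtract an estimated background from a signal
#'
#' @param signal,background numeric vectors of equal length.
#' @return Elementwise `signal - background`.
#' @export
subtract_background <- function(signal, background) {
  .check_numeric(signal, "signal")
  .check_numeric(background, "background")
  if (length(signal) != length(background))
    stop("signal and background must have equal length", call. = FALSE)
  signal - background
}

#' Local noise of a background-subtracted signal
#'
#' The signal noise is the standard deviation of the background-subtracted
#' samples in a moving window of `window_s` seconds (default 60 s = the
#' 1-min convention), centered and truncated at the edges like
#' [moving_median_background()].  The population convention (divide by the
#' window count `n`) is used.  With `robust = TRUE` a median-absolute-
#' deviation estimate (`1.4826 * MAD`, computed from two rolling medians)
#' is returned instead, which ignores sparse pulses entirely.
#'
#' @param signal background-subtracted sample vector.
#' @param sampling_hz sampling rate, samples/second.
#' @param window_s window length, seconds (> 0).
#' @param robust logical; use the MAD-based estimator.
#' @return An object of class `difc_noise_trace`: a list with elements
#'   `sampling_hz`, `sigma` (per-sample local noise, same length as
#'   `signal`), `window_s` and `robust`.
#' @export
moving_noise <- function(signal, sampling_hz, window_s = 60,
                         robust = FALSE) {
  .check_numeric(signal, "signal")
  .check_scalar(sampling_hz, "sampling_hz", lower = 0, strict_lower = TRUE)
  .check_scalar(window_s, "window_s", lower = 0, strict_lower = TRUE)
  L <- max(1L, as.integer(round(window_s * sampling_hz)))
  x <- as.numeric(signal)
  sigma <- if (isTRUE(robust)) {
    med <- .roll_median_trunc(x, L)
    1.4826 * .roll_median_trunc(abs(x - med), L)
  } else {
    .roll_sd_trunc(x, L)
  }
  structure(list(sampling_hz = sampling_hz, sigma = sigma,
                 window_s = window_s, robust = isTRUE(robust)),
            class = "difc_noise_trace")
}

#' @export
print.difc_noise_trace <- function(x, ...) {
  cat(sprintf("<difc_noise_trace> %d samples, %g s window%s, mean sigma %.4g\n",
              length(x$sigma), x$window_s,
              if (x$robust) " (robust MAD)" else "", mean(x$sigma)))
  invisible(x)
}
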