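#' Peak signal-to-noise ratio in decibels
#'
#' `snr_db(a, s) = 20 * log10(a / s)`.  With the detection threshold at
#' four times the local noise, the minimum SNR of a detected peak is
#' `20 * log10(4) = 12.04` dB.
#'
#' @param amplitude background-subtracted peak amplitude (> 0); vectorized.
#' @param noise local noise standard deviation (> 0); vectorized.
#' @return SNR in decibels.
#' @examples
#' snr_db(4, 1)   # 12.04 dB, the detection floor
#' @export
snr_db <- function(amplitude, noise) {
  if (!is.numeric(amplitude) || !is.numeric(noise) ||
      any(!is.finite(amplitude)) || any(!is.finite(noise)))
    stop("amplitude and noise must be finite numeric", call. = FALSE)
  if (any(amplitude <= 0) || any(noise <= 0))
    stop("amplitude and noise must be > 0", call. = FALSE)
  20 * log10(amplitude / noise)
}

# indices of local maxima: strictly greater than both neighboring distinct
# values; plateaus contribute their leftmost sample; record edges excluded
.local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  v <- r$values
  is_max <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] &
                v[2:(k - 1)] > v[3:k], FALSE)
  starts <- cumsum(c(1L, r$lengths[-k]))
  starts[is_max]
}

#' Detect peak candidates exceeding an adaptive noise threshold
#'
#' Peak candidates are local maxima of the background-subtracted signal
#' strictly exceeding `k` times the local noise at that sample (default
#' `k = 4`, i.e. a minimum SNR of 12.04 dB).  Candidates closer than
#' `min_separation_s` to a larger retained candidate are discarded, which
#' merges jitter-split maxima of a single transit.  With
#' `require_prominence = TRUE` (the default) a candidate must additionally
#' rise more than `k` times the local noise above the higher of its two
#' surrounding valleys (topographic prominence), which rejects noise
#' wiggles riding on the flanks of a larger pulse while leaving isolated
#' pulses untouched.
#'
#' @param signal background-subtracted sample vector.
#' @param noise a [moving_noise()] trace (or a numeric vector of per-sample
#'   noise values) aligned with `signal`.
#' @param sampling_hz sampling rate, samples/second.
#' @param k threshold multiplier (> 0), default 4.
#' @param min_separation_s minimum spacing between retained peaks, seconds.
#' @param probe probe label stored in the result (`"P1"` or `"P2"`).
#' @param require_prominence logical; apply the prominence criterion.
#' @param measure_widths logical; also measure each peak's FWHM with
#'   [measure_width()].
#' @return A data frame of class `difc_peaks`, one row per retained peak,
#'   sorted by time: columns `probe`, `index` (1-based sample index),
#'   `time_s`, `amplitude`, `local_noise`, `snr_db`, `prominence`,
#'   `width_s` (`NA` when not measurable).
#' @export
find_peak_candidates <- function(signal, noise, sampling_hz, k = 4,
                                 min_separation_s = 0.02, probe = "P1",
                                 require_prominence = TRUE,
                                 measure_widths = TRUE) {
  .check_numeric(signal, "signal")
  sigma <- if (inherits(noise, "difc_noise_trace")) noise$sigma else noise
  .check_numeric(sigma, "noise")
  if (length(sigma) != length(signal))
    stop("signal and noise trace must be aligned (equal length)",
         call. = FALSE)
  .check_scalar(sampling_hz, "sampling_hz", lower = 0, strict_lower = TRUE)
  .check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  .check_scalar(min_separation_s, "min_separation_s", lower = 0)

  x <- as.numeric(signal)
  idx <- .local_maxima(x)
  idx <- idx[x[idx] > k * sigma[idx]]
  prom <- NULL
  if (isTRUE(require_prominence) && length(idx)) {
    prom <- .peak_prominence(x, as.integer(idx))
    keep <- prom > k * sigma[idx]
    idx <- idx[keep]; prom <- prom[keep]
  }
  empty <- data.frame(probe = character(0), index = integer(0),
                      time_s = numeric(0), amplitude = numeric(0),
                      local_noise = numeric(0), snr_db = numeric(0),
                      prominence = numeric(0), width_s = numeric(0))
  class(empty) <- c("difc_peaks", "data.frame")
  if (length(idx) == 0L) return(empty)
  if (is.null(prom)) prom <- rep(NA_real_, length(idx))
  names(prom) <- idx

  # larger peaks win; ties go to the earlier peak
  ord <- order(-signal[idx], idx)
  min_sep <- min_separation_s * sampling_hz
  kept <- integer(0)
  for (i in idx[ord]) {
    if (length(kept) == 0L || all(abs(kept - i) >= min_sep))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  amp <- x[kept]
  loc <- as.numeric(sigma[kept])
  res <- data.frame(probe = probe, index = kept,
                    time_s = (kept - 1) / sampling_hz, amplitude = amp,
                    local_noise = loc,
                    snr_db = ifelse(loc > 0, 20 * log10(amp / loc), Inf),
                    prominence = as.numeric(prom[as.character(kept)]),
                    width_s = NA_real_)
  if (isTRUE(measure_widths) && nrow(res) > 0)
    res$width_s <- vapply(seq_len(nrow(res)), function(j)
      .fwhm_at(signal, res$index[j], sampling_hz, res$index), numeric(1))
  class(res) <- c("difc_peaks", "data.frame")
  res
}

# FWHM around sample index i by linear interpolation of the half-maximum
# crossings; NA if the record edge or a rise above the peak value is met
# before the crossing on either side
.fwhm_at <- function(signal, i, sampling_hz, all_idx = integer(0)) {
  amp <- signal[i]
  if (!is.finite(amp) || amp <= 0) return(NA_real_)
  half <- amp / 2
  n <- length(signal)
  cross <- function(step) {
    j <- i
    repeat {
      jn <- j + step
      if (jn < 1L || jn > n) return(NA_real_)      # record edge
      if (signal[jn] > amp) return(NA_real_)       # adjacent larger peak
      if (signal[jn] <= half) {
        # interpolate between j and jn
        f <- (signal[j] - half) / (signal[j] - signal[jn])
        return((j - 1) + step * f)
      }
      j <- jn
    }
  }
  left <- cross(-1L)
  right <- cross(+1L)
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) / sampling_hz
}

#' Measure a peak's full width at half maximum
#'
#' Walks outward from the peak sample to the first crossings of half the
#' peak amplitude and linearly interpolates the crossing instants.  The
#' width is reported as `NA` (absent) when a crossing is not found before
#' the record edge or before the signal rises above the peak value (an
#' adjacent larger peak).
#'
#' @param signal background-subtracted sample vector.
#' @param peak a one-row `difc_peaks` data frame (or a single sample
#'   index).
#' @param sampling_hz sampling rate, samples/second.
#' @return FWHM in seconds, or `NA_real_`.
#' @export
measure_width <- function(signal, peak, sampling_hz) {
  .check_numeric(signal, "signal")
  .check_scalar(sampling_hz, "sampling_hz", lower = 0, strict_lower = TRUE)
  i <- if (is.data.frame(peak)) {
    if (nrow(peak) != 1L) stop("peak must be a single row", call. = FALSE)
    as.integer(peak$index)
  } else as.integer(peak)
  if (i < 1L || i > length(signal))
    stop("peak index outside the record", call. = FALSE)
  .fwhm_at(signal, i, sampling_hz)
}

#' @export
print.difc_peaks <- function(x, ...) {
  cat(sprintf("<difc_peaks> %d peaks%s\n", nrow(x),
              if (nrow(x)) sprintf(" on %s, amplitude %.3g-%.3g",
                                   paste(unique(x$probe), collapse = "/"),
                                   min(x$amplitude), max(x$amplitude))
              else ""))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}

#' Write detected peaks to CSV
#' @param peaks a `difc_peaks` data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_peaks_csv <- function(peaks, path) {
  write.csv(as.data.frame(peaks)[, c("probe", "time_s", "amplitude",
                                     "local_noise", "snr_db", "width_s")],
            path, row.names = FALSE)
  invisible(path)
}
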