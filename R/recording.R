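#' Two-probe DiFC recording
#'
#' Container for a pair of aligned, uniformly sampled fluorescence channels
#' (probe P1 and probe P2) plus sampling metadata. This is the input to the
#' processing pipeline ([difc_process()]).
#'
#' @param sampling_hz sampling rate in samples per second.
#' @param p1,p2 numeric sample vectors of equal length (arbitrary signal
#'   units, typically volts).
#' @param units free-text unit label.
#' @param meta named list of provenance key/value pairs.
#'
#' @return An object of class `difc_recording`: a list with elements
#'   `sampling_hz`, `p1`, `p2`, `units`, `meta`.
#' @examples
#' rec <- difc_recording(100, sin(1:500 / 50), cos(1:500 / 50))
#' rec
#' @export
difc_recording <- function(sampling_hz, p1, p2, units = "a.u.",
                           meta = list()) {
  .check_scalar(sampling_hz, "sampling_hz", lower = 0, strict_lower = TRUE)
  .check_numeric(p1, "p1")
  .check_numeric(p2, "p2")
  if (length(p1) != length(p2))
    stop("p1 and p2 must have equal length", call. = FALSE)
  structure(list(sampling_hz = sampling_hz, p1 = as.numeric(p1),
                 p2 = as.numeric(p2), units = as.character(units)[1L],
                 meta = meta),
            class = "difc_recording")
}

#' @export
print.difc_recording <- function(x, ...) {
  cat(sprintf("<difc_recording> %d samples x 2 probes @ %g Hz (%.1f s), units: %s\n",
              length(x$p1), x$sampling_hz,
              length(x$p1) / x$sampling_hz, x$units))
  invisible(x)
}

#' @export
plot.difc_recording <- function(x, probes = c("p1", "p2"), ...) {
  t <- seq_along(x$p1) / x$sampling_hz
  op <- par(mfrow = c(length(probes), 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  for (p in probes)
    plot(t, x[[p]], type = "l", xlab = "time (s)",
         ylab = sprintf("%s (%s)", toupper(p), x$units), ...)
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a [difc_recording()].
#' @return Duration in seconds (`n_samples / sampling_hz`).
#' @export
recording_duration_s <- function(recording) {
  stopifnot(inherits(recording, "difc_recording"))
  length(recording$p1) / recording$sampling_hz
}

#' Read and write DiFC recordings
#'
#' The native plain-text dialect is a CSV file preceded by `#`-prefixed
#' header lines of the form `# key=value`.  The header must contain
#' `sampling_hz`; all other keys become metadata.  The body has columns
#' `time_s,p1,p2`.  The time column is redundant with `sampling_hz`; if the
#' two disagree the header wins and a warning is raised.  A write-then-read
#' round trip reproduces the samples bit-exactly.
#'
#' @param path file path.
#' @param recording a [difc_recording()].
#' @return `read_recording()` returns a [difc_recording()];
#'   `write_recording()` invisibly returns `path`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1L] - 1L else length(lines)
  hdr <- lines[seq_len(n_hdr)]
  meta <- list()
  for (h in hdr) {
    h <- sub("^#\\s*", "", h)
    if (!grepl("=", h, fixed = TRUE)) next
    key <- sub("=.*$", "", h)
    val <- sub("^[^=]*=", "", h)
    meta[[trimws(key)]] <- trimws(val)
  }
  if (is.null(meta$sampling_hz))
    stop("recording format error: missing required header key 'sampling_hz'",
         call. = FALSE)
  fs <- as.numeric(meta$sampling_hz)
  if (!is.finite(fs) || fs <= 0)
    stop("recording format error: invalid sampling_hz header", call. = FALSE)
  body <- lines[(n_hdr + 1L):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L)
    stop("recording format error: no data rows", call. = FALSE)
  if (!identical(trimws(body[1L]), "time_s,p1,p2"))
    stop("recording format error: expected column header 'time_s,p1,p2'",
         call. = FALSE)
  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  bad <- which(lengths(rows) != 3L)
  if (length(bad))
    stop(sprintf("recording format error: ragged row at line %d",
                 n_hdr + 1L + bad[1L]), call. = FALSE)
  m <- matrix(as.numeric(unlist(rows, use.names = FALSE)),
              ncol = 3L, byrow = TRUE)
  if (anyNA(m))
    stop("recording format error: non-numeric field in data rows",
         call. = FALSE)
  if (nrow(m) >= 2L) {
    dt <- diff(m[1:2, 1L])
    if (is.finite(dt) && dt > 0 && abs(dt - 1 / fs) > 1e-6 * (1 / fs))
      warning("time column step disagrees with sampling_hz header; header wins")
  }
  units <- if (is.null(meta$units)) "a.u." else meta$units
  meta$sampling_hz <- NULL
  meta$units <- NULL
  difc_recording(fs, m[, 2L], m[, 3L], units = units, meta = meta)
}

#' @rdname read_recording
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "difc_recording"))
  n <- length(recording$p1)
  hdr <- c("# difc recording v1",
           sprintf("# sampling_hz=%.17g", recording$sampling_hz),
           sprintf("# units=%s", recording$units))
  for (k in names(recording$meta))
    hdr <- c(hdr, sprintf("# %s=%s", k,
                          paste(format(recording$meta[[k]]), collapse = " ")))
  t <- (seq_len(n) - 1L) / recording$sampling_hz
  body <- sprintf("%.17g,%.17g,%.17g", t, recording$p1, recording$p2)
  writeLines(c(hdr, "time_s,p1,p2", body), path)
  invisible(path)
}
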