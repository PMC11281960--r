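#' Simulate a two-color flow-cytometry event table
#'
#' Emulates suspensions of green-stained (CFSE) cancer cells among
#' unstained blood cells measured on a benchtop cytometer: events are drawn
#' from a mixture of populations, each with log-normal green and NIR
#' intensity distributions (intensities are strictly positive, hence
#' log-displayable).
#'
#' @param populations list of populations; each a list with elements
#'   `label` (character), `fraction` (mixture weight; fractions must sum
#'   to 1 within 1e-9), `green` and `nir` (each `(log-mean, log-sd)`).
#' @param n number of events (>= 1).
#' @param seed integer seed; identical seeds give identical tables.
#' @return A data frame of class `difc_events` with columns `green`,
#'   `nir`, `label` and a `meta` attribute recording the generation
#'   parameters.
#' @examples
#' tbl <- simulate_events(list(
#'   list(label = "pbmc",  fraction = 0.99, green = c(0, 0.5),
#'        nir = c(0, 0.5)),
#'   list(label = "cancer", fraction = 0.01, green = c(4, 0.5),
#'        nir = c(4, 0.5))), n = 1000, seed = 1)
#' table(tbl$label)
#' @export
simulate_events <- function(populations, n, seed) {
  if (!is.list(populations) || length(populations) == 0L)
    stop("populations must be a non-empty list", call. = FALSE)
  .check_scalar(n, "n", lower = 1)
  .check_scalar(seed, "seed")
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  labs <- vapply(populations, function(p) as.character(p$label),
                 character(1))
  if (any(fr < 0)) stop("fractions must be >= 0", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("population fractions must sum to 1", call. = FALSE)
  for (p in populations) {
    .check_pair(p$green, "green")
    .check_pair(p$nir, "nir")
  }
  out <- with_seed(seed, {
    which_pop <- sample.int(length(populations), n, replace = TRUE,
                            prob = fr)
    green <- numeric(n); nir <- numeric(n)
    for (i in seq_along(populations)) {
      sel <- which_pop == i
      m <- sum(sel)
      if (m == 0L) next
      green[sel] <- rlnorm(m, populations[[i]]$green[1],
                           populations[[i]]$green[2])
      nir[sel] <- rlnorm(m, populations[[i]]$nir[1],
                         populations[[i]]$nir[2])
    }
    data.frame(green = green, nir = nir, label = labs[which_pop])
  })
  attr(out, "meta") <- list(populations = populations, n = n, seed = seed)
  class(out) <- c("difc_events", "data.frame")
  out
}

#' Quadrant gating of a two-color event table
#'
#' Splits events on a green and an NIR intensity threshold ("above
#' background" is strictly greater than): Q1 = green-only positive,
#' Q2 = double positive, Q3 = NIR-only positive, Q4 = double negative.
#' Fractions always sum to 1 over the (optionally label-restricted) event
#' set.
#'
#' @param table a `difc_events` data frame (or any data frame with
#'   `green`, `nir` and optionally `label` columns).
#' @param green_threshold,nir_threshold gating thresholds (> 0),
#'   intensity units.
#' @param subset optional population label; restrict gating to events with
#'   this label.
#' @return An object of class `difc_quadrants`: list with `q1`..`q4`
#'   (proportions), `green_threshold`, `nir_threshold`, `n_events`.
#' @export
quadrant_fractions <- function(table, green_threshold, nir_threshold,
                               subset = NULL) {
  if (!is.data.frame(table) || !all(c("green", "nir") %in% names(table)))
    stop("table must have `green` and `nir` columns", call. = FALSE)
  .check_scalar(green_threshold, "green_threshold", lower = 0,
                strict_lower = TRUE)
  .check_scalar(nir_threshold, "nir_threshold", lower = 0,
                strict_lower = TRUE)
  if (!is.null(subset)) {
    if (!"label" %in% names(table))
      stop("table has no `label` column to subset on", call. = FALSE)
    table <- table[table$label == subset, , drop = FALSE]
  }
  n <- nrow(table)
  if (n == 0L) stop("empty event selection", call. = FALSE)
  gpos <- table$green > green_threshold
  npos <- table$nir > nir_threshold
  structure(list(q1 = sum(gpos & !npos) / n,
                 q2 = sum(gpos & npos) / n,
                 q3 = sum(!gpos & npos) / n,
                 q4 = sum(!gpos & !npos) / n,
                 green_threshold = green_threshold,
                 nir_threshold = nir_threshold, n_events = n),
            class = "difc_quadrants")
}

#' @export
print.difc_quadrants <- function(x, ...) {
  cat(sprintf("<difc_quadrants> n = %d (green > %.3g, NIR > %.3g)\n",
              x$n_events, x$green_threshold, x$nir_threshold))
  cat(sprintf("  Q1 (green+ / NIR-): %5.1f%%\n", 100 * x$q1))
  cat(sprintf("  Q2 (green+ / NIR+): %5.1f%%\n", 100 * x$q2))
  cat(sprintf("  Q3 (green- / NIR+): %5.1f%%\n", 100 * x$q3))
  cat(sprintf("  Q4 (green- / NIR-): %5.1f%%\n", 100 * x$q4))
  invisible(x)
}

#' Ratio of mean intensities between two event tables
#'
#' @param table_a,table_b non-empty event tables.
#' @param channel `"green"` or `"nir"`.
#' @return Ratio of arithmetic means (`table_a` / `table_b`).
#' @export
mean_intensity_ratio <- function(table_a, table_b,
                                 channel = c("nir", "green")) {
  channel <- match.arg(channel)
  for (tb in list(table_a, table_b))
    if (!is.data.frame(tb) || nrow(tb) == 0L ||
        !channel %in% names(tb))
      stop("event tables must be non-empty with a `", channel,
           "` column", call. = FALSE)
  mean(table_a[[channel]]) / mean(table_b[[channel]])
}

#' @export
plot.difc_events <- function(x, green_threshold = NULL,
                             nir_threshold = NULL, ...) {
  cols <- seq_along(unique(x$label))
  names(cols) <- unique(x$label)
  plot(x$nir, x$green, log = "xy", pch = ".",
       col = adjustcolor(cols[x$label], 0.5),
       xlab = "NIR intensity (a.u.)", ylab = "green intensity (a.u.)", ...)
  if (!is.null(nir_threshold)) abline(v = nir_threshold, lwd = 2)
  if (!is.null(green_threshold)) abline(h = green_threshold, lwd = 2)
  legend("topleft", legend = names(cols), col = cols, pch = 16, bty = "n")
  invisible(x)
}

#' Read and write event tables as CSV
#'
#' Columns `green`, `nir`, `label`.
#' @param table a `difc_events` data frame.
#' @param path file path.
#' @return `read_events_csv()` returns a `difc_events` data frame.
#' @export
write_events_csv <- function(table, path) {
  write.csv(as.data.frame(table)[, c("green", "nir", "label")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("green", "nir") %in% names(x)))
    stop("event CSV must have `green` and `nir` columns", call. = FALSE)
  if (!"label" %in% names(x)) x$label <- "events"
  class(x) <- c("difc_events", "data.frame")
  x
}
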