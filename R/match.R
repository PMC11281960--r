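#' Match P1/P2 peak candidates into cell detections
#'
#' A cell passing under both probes produces a peak on each, separated by
#' the transit delay over the 3 mm probe spacing.  Candidate peaks from the
#' two probes are paired when their time difference lies within
#' `delay_bounds_s`; among admissible pairings the assignment maximizes the
#' number of matched cells and, among those, minimizes the total absolute
#' delay, with exact ties resolved by the smaller total squared delay
#' (each peak used at most once).  At rare-event densities the
#' admissible-pair graph splits into tiny connected components, which are
#' solved exactly; this resolves near-coincident transits that a purely
#' greedy smallest-delay rule would cross-pair.  A pair with the P1 peak
#' first is a forward (arterial) detection; P2 first is reverse (venous).
#' Peaks left unpaired are counted and excluded from all downstream cell
#' statistics; pairs closer than the lower delay bound are treated as
#' electrically coincident artifacts and never matched.
#'
#' @param peaks_p1,peaks_p2 `difc_peaks` data frames (from
#'   [find_peak_candidates()]), sorted by time.
#' @param delay_bounds_s numeric pair `(min, max)` of admissible absolute
#'   delays, seconds; `0 < min < max`.
#' @param probe_separation_mm probe separation used for speed estimation.
#' @return An object of class `difc_match`: list with `matched` (data
#'   frame: `t_p1`, `t_p2`, `direction`, `delay_s`, `speed_mm_s`,
#'   `amplitude_p1`, `amplitude_p2`, `snr_db_p1`, `snr_db_p2`, `width_p1_s`,
#'   `width_p2_s`), `unmatched_p1`, `unmatched_p2` (counts) and the bounds.
#' @examples
#' p1 <- data.frame(probe = "P1", index = 5001L, time_s = 10.000,
#'                  amplitude = 1, local_noise = 0.1, snr_db = 20,
#'                  width_s = NA_real_)
#' p2 <- p1; p2$probe <- "P2"; p2$time_s <- 10.030; p2$index <- 5016L
#' match_peaks(p1, p2)$matched$speed_mm_s  # 100 mm/s over 3 mm
#' @export
match_peaks <- function(peaks_p1, peaks_p2, delay_bounds_s = c(0.005, 0.5),
                        probe_separation_mm = 3.0) {
  .check_pair(delay_bounds_s, "delay_bounds_s")
  if (delay_bounds_s[1] <= 0 || delay_bounds_s[1] >= delay_bounds_s[2])
    stop("delay bounds must satisfy 0 < min < max", call. = FALSE)
  .check_scalar(probe_separation_mm, "probe_separation_mm", lower = 0,
                strict_lower = TRUE)
  t1 <- peaks_p1$time_s
  t2 <- peaks_p2$time_s
  if (is.unsorted(t1) || is.unsorted(t2))
    stop("peak lists must be sorted by time", call. = FALSE)

  n1 <- length(t1); n2 <- length(t2)
  pairs <- NULL
  if (n1 > 0 && n2 > 0) {
    dt <- abs(outer(t1, t2, "-"))
    ok <- which(dt >= delay_bounds_s[1] & dt <= delay_bounds_s[2],
                arr.ind = TRUE)
    if (nrow(ok) > 0)
      pairs <- data.frame(i = ok[, 1L], j = ok[, 2L],
                          adt = dt[ok])
  }
  used1 <- logical(n1); used2 <- logical(n2)
  sel_i <- integer(0); sel_j <- integer(0)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    pairs <- pairs[order(pairs$adt, t1[pairs$i], t2[pairs$j]), , drop = FALSE]
    sel <- .assign_pairs(pairs, n1, n2)
    sel_i <- pairs$i[sel]; sel_j <- pairs$j[sel]
    used1[sel_i] <- TRUE; used2[sel_j] <- TRUE
  }
  if (length(sel_i)) {
    ord <- order(pmin(t1[sel_i], t2[sel_j]))
    sel_i <- sel_i[ord]; sel_j <- sel_j[ord]
    delay <- abs(t2[sel_j] - t1[sel_i])
    matched <- data.frame(
      t_p1 = t1[sel_i], t_p2 = t2[sel_j],
      direction = ifelse(t1[sel_i] < t2[sel_j], "forward", "reverse"),
      delay_s = delay,
      speed_mm_s = probe_separation_mm / delay,
      amplitude_p1 = peaks_p1$amplitude[sel_i],
      amplitude_p2 = peaks_p2$amplitude[sel_j],
      snr_db_p1 = peaks_p1$snr_db[sel_i],
      snr_db_p2 = peaks_p2$snr_db[sel_j],
      width_p1_s = peaks_p1$width_s[sel_i],
      width_p2_s = peaks_p2$width_s[sel_j])
  } else {
    matched <- data.frame(t_p1 = numeric(0), t_p2 = numeric(0),
                          direction = character(0), delay_s = numeric(0),
                          speed_mm_s = numeric(0),
                          amplitude_p1 = numeric(0),
                          amplitude_p2 = numeric(0),
                          snr_db_p1 = numeric(0), snr_db_p2 = numeric(0),
                          width_p1_s = numeric(0), width_p2_s = numeric(0))
  }
  structure(list(matched = matched,
                 unmatched_p1 = sum(!used1), unmatched_p2 = sum(!used2),
                 delay_bounds_s = delay_bounds_s,
                 probe_separation_mm = probe_separation_mm),
            class = "difc_match")
}

# Maximum-cardinality, minimum-total-delay assignment of admissible pairs.
# `pairs` has columns i (P1 index), j (P2 index), adt (absolute delay),
# sorted by ascending adt.  Connected components of the pair graph are
# solved by exact search (they are tiny when events are rare); a component
# too large for exact search falls back to greedy ascending-delay within
# that component.  Returns row indices of `pairs` selected.
.assign_pairs <- function(pairs, n1, n2, max_exact_nodes = 16L) {
  parent <- seq_len(n1 + n2)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs$i[r]); rb <- find(n1 + pairs$j[r])
    if (ra != rb) parent[rb] <- ra
  }
  comp_of_pair <- vapply(seq_len(nrow(pairs)),
                         function(r) find(pairs$i[r]), integer(1))
  selected <- integer(0)
  for (comp in unique(comp_of_pair)) {
    rows <- which(comp_of_pair == comp)
    sub <- pairs[rows, , drop = FALSE]
    lefts <- unique(sub$i); rights <- unique(sub$j)
    if (length(lefts) + length(rights) <= max_exact_nodes) {
      sel <- .match_component_exact(sub)
    } else {
      sel <- .match_component_greedy(sub)
    }
    selected <- c(selected, rows[sel])
  }
  selected
}

.match_component_greedy <- function(sub) {
  u1 <- character(0); u2 <- character(0)
  sel <- integer(0)
  for (r in seq_len(nrow(sub))) {
    ci <- as.character(sub$i[r]); cj <- as.character(sub$j[r])
    if (!(ci %in% u1) && !(cj %in% u2)) {
      u1 <- c(u1, ci); u2 <- c(u2, cj)
      sel <- c(sel, r)
    }
  }
  sel
}

# Exact search: maximize cardinality, then minimize total |delay|; exact
# ties in the total (e.g. two same-direction transits whose P2 peaks both
# precede both P1 peaks, where every pairing has the same total) are
# resolved by the smaller total squared delay, which favors delays drawn
# from a common speed mode over one short + one long delay.
.match_component_exact <- function(sub) {
  lefts <- sort(unique(sub$i))
  by_left <- lapply(lefts, function(l) which(sub$i == l))
  n_left <- length(lefts)
  best_sel <- integer(0); best_card <- -1L
  best_cost <- Inf; best_cost2 <- Inf
  rec <- function(li, used_j, sel, cost, cost2) {
    card <- length(sel)
    if (card + (n_left - li + 1L) < best_card) return()  # cannot win
    if (li > n_left) {
      better <- card > best_card ||
        (card == best_card &&
           (cost < best_cost - 1e-9 ||
              (abs(cost - best_cost) <= 1e-9 && cost2 < best_cost2)))
      if (better) {
        best_sel <<- sel; best_card <<- card
        best_cost <<- cost; best_cost2 <<- cost2
      }
      return()
    }
    for (r in by_left[[li]]) {         # ascending delay within this left
      j <- sub$j[r]
      if (!(j %in% used_j))
        rec(li + 1L, c(used_j, j), c(sel, r), cost + sub$adt[r],
            cost2 + sub$adt[r]^2)
    }
    rec(li + 1L, used_j, sel, cost, cost2)  # leave this peak unmatched
  }
  rec(1L, integer(0), integer(0), 0, 0)
  best_sel
}

#' @export
print.difc_match <- function(x, ...) {
  m <- x$matched
  cat(sprintf("<difc_match> %d matched (%d forward / %d reverse), unmatched P1: %d, P2: %d\n",
              nrow(m), sum(m$direction == "forward"),
              sum(m$direction == "reverse"),
              x$unmatched_p1, x$unmatched_p2))
  invisible(x)
}

#' Flow speed from inter-probe delay
#'
#' @param delay_s inter-probe transit delay, seconds (> 0); vectorized.
#' @param probe_separation_mm probe separation, millimeters.
#' @return Speed in mm/s (`probe_separation_mm / delay_s`).
#' @examples
#' estimate_speed(0.030, 3)  # 100 mm/s
#' @export
estimate_speed <- function(delay_s, probe_separation_mm = 3.0) {
  if (!is.numeric(delay_s) || any(!is.finite(delay_s)) || any(delay_s <= 0))
    stop("delay_s must be finite and > 0", call. = FALSE)
  .check_scalar(probe_separation_mm, "probe_separation_mm", lower = 0,
                strict_lower = TRUE)
  probe_separation_mm / delay_s
}

#' Score a scan result against simulation ground truth
#'
#' A matched detection is a true positive when some ground-truth transit
#' has both probe times within `time_tolerance_s` of the detection's peak
#' times; each truth transit is credited at most once (detections are
#' considered in time order).  When both the result and the truth are
#' empty, recall and precision are 1 by convention (vacuously perfect).
#'
#' @param result a `difc_scan` or `difc_match` object.
#' @param truth a `difc_truth` object from [simulate_recording()].
#' @param time_tolerance_s matching tolerance, seconds.
#' @return A list: `recall`, `precision`, `direction_accuracy`,
#'   `speed_rmse_mm_s`, `n_truth`, `n_matched`, `true_positives`.
#' @export
evaluate_against_truth <- function(result, truth, time_tolerance_s = 0.05) {
  stopifnot(inherits(truth, "difc_truth"))
  m <- if (inherits(result, "difc_scan") || inherits(result, "difc_match"))
    result$matched else result
  tr <- truth$transits
  n_truth <- nrow(tr); n_matched <- nrow(m)
  if (n_truth == 0L && n_matched == 0L)
    return(list(recall = 1.0, precision = 1.0, direction_accuracy = 1.0,
                speed_rmse_mm_s = 0.0, n_truth = 0L, n_matched = 0L,
                true_positives = 0L))
  credited <- logical(n_truth)
  tp <- 0L; dir_ok <- 0L; sqerr <- numeric(0)
  if (n_matched > 0L) for (i in seq_len(n_matched)) {
    if (n_truth == 0L) break
    cand <- which(!credited &
                    abs(tr$t_p1 - m$t_p1[i]) <= time_tolerance_s &
                    abs(tr$t_p2 - m$t_p2[i]) <= time_tolerance_s)
    if (length(cand)) {
      j <- cand[which.min(abs(tr$t_p1[cand] - m$t_p1[i]) +
                            abs(tr$t_p2[cand] - m$t_p2[i]))]
      credited[j] <- TRUE
      tp <- tp + 1L
      if (identical(tr$direction[j], m$direction[i])) dir_ok <- dir_ok + 1L
      sqerr <- c(sqerr, (tr$speed_mm_s[j] - m$speed_mm_s[i])^2)
    }
  }
  list(recall = if (n_truth) tp / n_truth else 1.0,
       precision = if (n_matched) tp / n_matched else 1.0,
       direction_accuracy = if (tp) dir_ok / tp else 1.0,
       speed_rmse_mm_s = if (tp) sqrt(mean(sqerr)) else 0.0,
       n_truth = n_truth, n_matched = n_matched, true_positives = tp)
}
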