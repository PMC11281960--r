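test_that("single pairs match with the right direction, delay and speed", {
  fwd <- match_peaks(peaks_df(10.000), peaks_df(10.030, "P2"))
  expect_identical(nrow(fwd$matched), 1L)
  expect_identical(fwd$matched$direction, "forward")
  expect_equal(fwd$matched$delay_s, 0.030, tolerance = 1e-12)
  expect_equal(fwd$matched$speed_mm_s, 100, tolerance = 1e-9)

  rev <- match_peaks(peaks_df(10.100), peaks_df(10.000, "P2"))
  expect_identical(rev$matched$direction, "reverse")
  expect_equal(rev$matched$speed_mm_s, 30, tolerance = 1e-9)

  # a peak seen on one probe only is discarded as unmatched
  lone <- match_peaks(peaks_df(10), peaks_df(numeric(0), "P2"))
  expect_identical(nrow(lone$matched), 0L)
  expect_identical(lone$unmatched_p1, 1L)

  expect_error(match_peaks(peaks_df(c(3, 1)), peaks_df(2, "P2")), "sorted")
  expect_error(match_peaks(peaks_df(1), peaks_df(2, "P2"),
                           delay_bounds_s = c(0.5, 0.1)), "bounds")
})

test_that("pairs outside the delay bounds never match", {
  # below the minimum bound: coincident artifact, both stay unmatched
  res <- match_peaks(peaks_df(10.000), peaks_df(10.002, "P2"))
  expect_identical(nrow(res$matched), 0L)
  expect_identical(res$unmatched_p1 + res$unmatched_p2, 2L)
  # beyond the maximum bound
  res2 <- match_peaks(peaks_df(10), peaks_df(11, "P2"))
  expect_identical(nrow(res2$matched), 0L)
})

test_that("the assignment achieves maximum cardinality on random instances", {
  # compared with an independent maximum-cardinality bipartite matching
  # oracle (Kuhn augmenting paths)
  set.seed(314)
  bounds <- c(0.005, 0.5)
  for (inst in 1:120) {
    t1 <- sort(runif(10, 0, 60))
    t2 <- sort(runif(10, 0, 60))
    res <- match_peaks(peaks_df(t1), peaks_df(t2, "P2"),
                       delay_bounds_s = bounds)
    adj <- lapply(seq_along(t1), function(i) {
      dt <- abs(t1[i] - t2)
      which(dt >= bounds[1] & dt <= bounds[2])
    })
    expect_identical(nrow(res$matched), bf_max_matching(adj, length(t2)))
  }
})

test_that("near-coincident transits are paired by total delay, not locally smallest delay", {
  # two reverse transits 0.3 s apart: the cross pair has the smallest
  # single delay (0.096 s) but the correct assignment minimizes the total
  t1 <- c(7.163, 7.453)
  t2 <- c(7.022, 7.257)
  res <- match_peaks(peaks_df(t1), peaks_df(t2, "P2"))
  expect_identical(nrow(res$matched), 2L)
  expect_identical(res$matched$direction, c("reverse", "reverse"))
  expect_equal(res$matched$delay_s, c(7.163 - 7.022, 7.453 - 7.257),
               tolerance = 1e-9)
})

test_that("matching output invariants hold on random instances", {
  set.seed(2718)
  for (inst in 1:25) {
    n1 <- sample(0:15, 1); n2 <- sample(0:15, 1)
    t1 <- sort(runif(n1, 0, 30)); t2 <- sort(runif(n2, 0, 30))
    res <- match_peaks(peaks_df(t1), peaks_df(t2, "P2"))
    m <- res$matched
    # conservation of peaks
    expect_identical(2L * nrow(m) + res$unmatched_p1 + res$unmatched_p2,
                     n1 + n2)
    if (nrow(m)) {
      expect_true(all(m$delay_s >= 0.005 & m$delay_s <= 0.5))
      expect_identical(m$direction == "forward", m$t_p1 < m$t_p2)
      expect_equal(m$delay_s, abs(m$t_p2 - m$t_p1), tolerance = 1e-12)
      expect_equal(m$speed_mm_s, 3 / m$delay_s, tolerance = 1e-12)
      # no peak used twice
      expect_identical(anyDuplicated(m$t_p1), 0L)
      expect_identical(anyDuplicated(m$t_p2), 0L)
    }
  }
})

test_that("speed estimation is separation over delay with a clean inverse", {
  expect_equal(estimate_speed(0.030, 3), 100, tolerance = 1e-12)
  expect_equal(estimate_speed(0.150, 3), 20, tolerance = 1e-12)
  d <- 0.0734
  expect_equal(3 / estimate_speed(d, 3), d, tolerance = 1e-12)
  expect_error(estimate_speed(0, 3), "> 0")
  expect_error(estimate_speed(-0.1, 3), "> 0")
})

test_that("scoring against ground truth counts hits, misses and spurious detections", {
  empty_truth <- structure(list(transits = data.frame(
    t_p1 = numeric(0), t_p2 = numeric(0), direction = character(0),
    speed_mm_s = numeric(0), amplitude = numeric(0), width_s = numeric(0)),
    artifacts = data.frame(), duration_s = 60), class = "difc_truth")
  empty_res <- match_peaks(peaks_df(numeric(0)), peaks_df(numeric(0), "P2"))
  ev0 <- evaluate_against_truth(empty_res, empty_truth)
  expect_identical(ev0$recall, 1.0)
  expect_identical(ev0$precision, 1.0)

  # truth with 10 transits; result reproduces 9 plus 1 spurious
  t_p1 <- seq(5, 50, by = 5)
  truth <- structure(list(transits = data.frame(
    t_p1 = t_p1, t_p2 = t_p1 + 0.03, direction = "forward",
    speed_mm_s = 100, amplitude = 1, width_s = 0.01),
    artifacts = data.frame(), duration_s = 60), class = "difc_truth")
  res <- match_peaks(peaks_df(c(t_p1[1:9], 57)),
                     peaks_df(c(t_p1[1:9] + 0.03, 57.2), "P2"))
  ev <- evaluate_against_truth(res, truth, time_tolerance_s = 0.01)
  expect_equal(ev$recall, 0.9, tolerance = 1e-12)
  expect_equal(ev$precision, 0.9, tolerance = 1e-12)
  expect_identical(ev$direction_accuracy, 1.0)

  # perfect reproduction scores 1 everywhere
  res_full <- match_peaks(peaks_df(t_p1), peaks_df(t_p1 + 0.03, "P2"))
  ev_full <- evaluate_against_truth(res_full, truth, time_tolerance_s = 0.01)
  expect_identical(ev_full$recall, 1.0)
  expect_identical(ev_full$precision, 1.0)
  expect_lt(ev_full$speed_rmse_mm_s, 1e-6)
})
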