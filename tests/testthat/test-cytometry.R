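two_pop <- function(minority = 0.01, nir_cancer = c(4, 0.5)) {
  list(list(label = "pbmc", fraction = 1 - minority,
            green = c(0, 0.5), nir = c(0, 0.5)),
       list(label = "cancer", fraction = minority,
            green = c(4, 0.5), nir = nir_cancer))
}

test_that("event simulation respects mixture fractions and determinism", {
  one <- simulate_events(list(list(label = "only", fraction = 1,
                                   green = c(1, 0.3), nir = c(2, 0.3))),
                         n = 1000, seed = 1)
  expect_identical(nrow(one), 1000L)
  expect_true(all(one$label == "only"))
  expect_true(all(one$green > 0 & one$nir > 0))

  big <- simulate_events(two_pop(0.01), n = 1e5, seed = 2)
  minority <- sum(big$label == "cancer")
  expect_lt(abs(minority - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))

  expect_identical(simulate_events(two_pop(), 500, seed = 3),
                   simulate_events(two_pop(), 500, seed = 3))
  bad <- two_pop(); bad[[1]]$fraction <- 0.5
  expect_error(simulate_events(bad, 100, seed = 1), "sum to 1")
})

test_that("quadrant fractions count strictly-positive events and sum to one", {
  tbl <- data.frame(green = c(10, 10, 0.1, 0.1), nir = c(10, 0.1, 10, 0.1),
                    label = "x")
  q <- quadrant_fractions(tbl, 1, 1)
  expect_equal(c(q$q1, q$q2, q$q3, q$q4), c(0.25, 0.25, 0.25, 0.25))
  # all-negative case
  low <- data.frame(green = rep(0.1, 5), nir = rep(0.2, 5))
  expect_identical(quadrant_fractions(low, 1, 1)$q4, 1)
  # boundary events are negative (strictly greater than)
  onb <- data.frame(green = 1, nir = 1)
  expect_identical(quadrant_fractions(onb, 1, 1)$q4, 1)
  expect_error(quadrant_fractions(tbl, 1, 1, subset = "missing"), "empty")
})

test_that("quadrant fractions are invariant under joint monotone transforms", {
  tbl <- simulate_events(two_pop(0.2), n = 2000, seed = 8)
  q_raw <- quadrant_fractions(tbl, 5, 5)
  tbl2 <- tbl
  tbl2$green <- tbl$green^2
  tbl2$nir <- exp(tbl$nir)
  q_tr <- quadrant_fractions(tbl2, 25, exp(5))
  expect_equal(c(q_raw$q1, q_raw$q2, q_raw$q3, q_raw$q4),
               c(q_tr$q1, q_tr$q2, q_tr$q3, q_tr$q4), tolerance = 1e-12)
  expect_equal(q_raw$q1 + q_raw$q2 + q_raw$q3 + q_raw$q4, 1,
               tolerance = 1e-9)
})

test_that("label restriction equals brute-force filtering then gating", {
  tbl <- simulate_events(two_pop(0.3), n = 5000, seed = 12)
  q_sub <- quadrant_fractions(tbl, 2, 2, subset = "cancer")
  manual <- quadrant_fractions(tbl[tbl$label == "cancer", ], 2, 2)
  expect_equal(c(q_sub$q1, q_sub$q2, q_sub$q3, q_sub$q4),
               c(manual$q1, manual$q2, manual$q3, manual$q4))
  expect_identical(q_sub$n_events, sum(tbl$label == "cancer"))
})

test_that("double-positive fraction matches the closed-form log-normal tail", {
  # NIR log-mean placed so that P(NIR > threshold) = 0.83 for the labeled
  # cancer population; green is far above its threshold
  nt <- 5
  sdlog <- 0.8
  mu <- log(nt) - sdlog * qnorm(1 - 0.83)
  tbl <- simulate_events(two_pop(0.5, nir_cancer = c(mu, sdlog)),
                         n = 1e5, seed = 21)
  q2 <- quadrant_fractions(tbl, 1, nt, subset = "cancer")$q2
  expect_lt(abs(q2 - 0.83), 0.02)
})

test_that("labeling blockade drives the double-positive fraction to the autofluorescence tail", {
  # NIR labeling efficiency -> 0: the cancer population keeps only its
  # autofluorescence, so Q2 collapses to that distribution's tail
  blocked <- two_pop(0.5, nir_cancer = c(0, 0.5))
  tbl <- simulate_events(blocked, n = 5e4, seed = 30)
  q2 <- quadrant_fractions(tbl, 1, 5, subset = "cancer")$q2
  tail_af <- plnorm(5, 0, 0.5, lower.tail = FALSE)
  expect_lt(abs(q2 - tail_af), 0.01)
  expect_lt(q2, 0.05)
})

test_that("mean intensity ratios scale and match the log-normal mean formula", {
  tbl <- simulate_events(two_pop(0.5), n = 2000, seed = 4)
  expect_identical(mean_intensity_ratio(tbl, tbl, "nir"), 1)
  bright <- tbl
  bright$nir <- tbl$nir * 5.6
  expect_equal(mean_intensity_ratio(bright, tbl, "nir"), 5.6,
               tolerance = 1e-9)
  # closed form: E[lognormal(mu, s)] = exp(mu + s^2/2)
  a <- simulate_events(list(list(label = "a", fraction = 1,
                                 green = c(0, 0.1), nir = c(3, 0.6))),
                       n = 2e5, seed = 5)
  b <- simulate_events(list(list(label = "b", fraction = 1,
                                 green = c(0, 0.1), nir = c(1, 0.3))),
                       n = 2e5, seed = 6)
  closed <- exp((3 + 0.6^2 / 2) - (1 + 0.3^2 / 2))
  expect_lt(abs(mean_intensity_ratio(a, b, "nir") / closed - 1), 0.02)
  expect_error(mean_intensity_ratio(tbl[0, ], tbl, "nir"), "non-empty")
})

test_that("event tables round-trip through CSV", {
  tbl <- simulate_events(two_pop(0.1), n = 200, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(tbl, path)
  back <- read_events_csv(path)
  expect_equal(back$green, tbl$green, tolerance = 1e-12)
  expect_equal(back$nir, tbl$nir, tolerance = 1e-12)
  expect_identical(back$label, tbl$label)
})
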