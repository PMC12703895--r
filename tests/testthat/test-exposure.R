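dates_n <- function(n, from = "2010-06-01") {
  seq(as.Date(from), by = "day", length.out = n)
}

test_that("percentile threshold interpolates between order statistics", {
  d <- dates_n(9)
  expect_equal(compute_threshold(d, rep(30, 9),
                                 heatwave_definition(percentile = 77)), 30)
  expect_equal(compute_threshold(d, 1:9,
                                 heatwave_definition(percentile = 92.5)), 8.4)
  expect_equal(compute_threshold(d, 1:9,
                                 heatwave_definition(percentile = 50)), 5)
})

test_that("threshold respects reference period and season restrictions", {
  d <- seq(as.Date("2010-01-01"), as.Date("2011-12-31"), by = "day")
  v <- ifelse(as.integer(format(d, "%m")) %in% 5:9, 30, 0)
  warm <- compute_threshold(d, v, heatwave_definition(percentile = 50))
  all_year <- compute_threshold(
    d, v, heatwave_definition(percentile = 50, threshold_season = "all"))
  expect_equal(warm, 30)
  expect_lt(all_year, 30)
  only_2010 <- compute_threshold(
    d, ifelse(as.integer(format(d, "%Y")) == 2010, v, v + 5),
    heatwave_definition(percentile = 50, reference_period = 2010))
  expect_equal(only_2010, 30)
})

test_that("threshold excludes missing days with a message and errors when empty", {
  d <- dates_n(10)
  v <- c(1:9, NA)
  expect_message(thr <- compute_threshold(d, v, heatwave_definition(percentile = 50)),
                 "1 missing")
  expect_equal(thr, 5)
  expect_error(compute_threshold(d, rep(NA_real_, 10),
                                 heatwave_definition()), "no data")
})

test_that("detection finds maximal strict-exceedance runs of sufficient length", {
  d <- dates_n(6)
  expect_equal(nrow(detect_heatwaves(d, rep(20, 6), 32, 2)), 0L)
  ev <- detect_heatwaves(d, c(30, 33, 34, 31, 35, 30), 32, 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, d[2])
  expect_equal(ev$end, d[3])
  expect_equal(ev$duration, 2L)
  expect_equal(ev$excess_degree_days, 3)
  ev2 <- detect_heatwaves(dates_n(3), c(33, 33, 33), 32, 2)
  expect_equal(ev2$duration, 3L)
  expect_equal(ev2$excess_degree_days, 3)
  # ties at the threshold do not count (strict exceedance)
  expect_equal(nrow(detect_heatwaves(dates_n(3), c(32, 32, 32), 32, 2)), 0L)
})

test_that("runs never bridge the gap between warm seasons", {
  d <- c(seq(as.Date("2010-09-27"), as.Date("2010-09-30"), by = "day"),
         seq(as.Date("2011-05-01"), as.Date("2011-05-02"), by = "day"))
  ev <- detect_heatwaves(d, rep(40, 6), 32, 2)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$duration, c(4L, 2L))
})

test_that("non-monotonic dates are rejected", {
  d <- dates_n(5)[c(1, 3, 2, 4, 5)]
  expect_error(detect_heatwaves(d, rep(40, 5), 32, 2), "increasing")
})

test_that("detection matches brute-force run enumeration on random series", {
  set.seed(101)
  for (i in 1:200) {
    rs <- random_series()
    thr <- stats::quantile(rs$values, 0.9)
    md <- sample(1:3, 1)
    ev <- detect_heatwaves(rs$dates, rs$values, thr, md)
    bf <- brute_force_runs(rs$dates, rs$values, thr, md)
    expect_equal(nrow(ev), nrow(bf))
    if (nrow(ev)) {
      expect_equal(ev$start, bf$start)
      expect_equal(ev$end, bf$end)
      expect_equal(ev$duration, bf$duration)
      expect_equal(ev$excess_degree_days, bf$excess, tolerance = 1e-12)
    }
  }
})

test_that("indicator marks exactly the event days and sums to total duration", {
  d <- dates_n(20)
  expect_identical(heatwave_day_indicator(detect_heatwaves(d, rep(0, 20), 1, 2), d),
                   integer(20))
  v <- rep(30, 20); v[5:6] <- 35; v[10:12] <- 36
  ev <- detect_heatwaves(d, v, 32, 2)
  ind <- heatwave_day_indicator(ev, d)
  expect_equal(which(ind == 1L), c(5:6, 10:12))
  expect_equal(sum(ind), sum(ev$duration))
  es <- exposure_summary(ev, 2010)
  expect_equal(es$n_heatwave_days, sum(ind))
  expect_equal(es$n_events, 2L)
})

test_that("overlapping events are rejected", {
  ev <- data.frame(location_id = "a",
                   start = as.Date(c("2010-06-01", "2010-06-03")),
                   end = as.Date(c("2010-06-04", "2010-06-05")),
                   duration = c(4L, 3L), mean_metric = 30,
                   excess_degree_days = 1)
  expect_error(heatwave_day_indicator(ev, dates_n(10)), "overlap")
})

test_that("CEDD is additive over events and splits", {
  expect_equal(compute_cedd(detect_heatwaves(dates_n(3), rep(0, 3), 1, 2)), 0)
  set.seed(7)
  for (i in 1:20) {
    rs <- random_series(n_years = 1)
    thr <- stats::quantile(rs$values, 0.88)
    ev <- detect_heatwaves(rs$dates, rs$values, thr, 2)
    expect_equal(compute_cedd(ev), sum(ev$excess_degree_days))
    # split the year at a non-heatwave day: totals unchanged
    ind <- heatwave_day_indicator(ev, rs$dates)
    cut <- which(ind == 0 & as.integer(format(rs$dates, "%m")) %in% 6:8)[1]
    a <- detect_heatwaves(rs$dates[1:cut], rs$values[1:cut], thr, 2)
    n <- length(rs$dates)
    b <- detect_heatwaves(rs$dates[(cut + 1):n], rs$values[(cut + 1):n], thr, 2)
    expect_equal(compute_cedd(a) + compute_cedd(b), compute_cedd(ev),
                 tolerance = 1e-12)
  }
})

test_that("raising the percentile never lowers the threshold or adds heatwave days", {
  set.seed(31)
  rs <- random_series()
  defs <- lapply(c(85, 90, 92.5, 95, 97.5),
                 function(p) heatwave_definition(percentile = p))
  thr <- vapply(defs, function(dd) compute_threshold(rs$dates, rs$values, dd),
                numeric(1))
  expect_true(all(diff(thr) >= 0))
  hw <- vapply(thr, function(t2) {
    sum(detect_heatwaves(rs$dates, rs$values, t2, 2)$duration)
  }, numeric(1))
  expect_true(all(diff(hw) <= 0))
})

test_that("person-days is the exact product and scales linearly", {
  expect_equal(compute_person_days(0, 5e6), 0)
  expect_equal(compute_person_days(3, 1000), 3000)
  expect_equal(compute_person_days(7, 2 * 12345), 2 * compute_person_days(7, 12345))
  expect_error(compute_person_days(-1, 10), "nonnegative")
})

test_that("heat index behaves like the NWS apparent temperature", {
  expect_equal(heatburden:::fahrenheit_to_celsius(
    heatburden:::celsius_to_fahrenheit(23.456)), 23.456, tolerance = 1e-9)
  expect_lt(abs(heat_index(20, 50) - 20), 1)
  expect_gt(heat_index(35, 80), heat_index(35, 40))
  expect_error(heat_index(30, 120), "rh")
})

test_that("target-vs-baseline comparison computes exact differences and a t-test", {
  cmp <- compare_exposure(c(5, 5, 5), 5)
  expect_equal(cmp$difference, 0)
  cmp2 <- compare_exposure(c(1, 2, 3), 10)
  expect_equal(cmp2$difference, 8)
  expect_equal(cmp2$p_value, stats::t.test(c(1, 2, 3), mu = 10)$p.value)
  expect_error(compare_exposure(1, 10), "baseline")
})

test_that("exposure summary reports person-days per population group", {
  d <- dates_n(20)
  v <- rep(30, 20); v[5:8] <- 35
  ev <- detect_heatwaves(d, v, 32, 2)
  pop <- data.frame(year = 2010, pop_total = 1000, pop_65p = 100)
  es <- exposure_summary(ev, 2010, pop)
  expect_equal(es$person_days_total, 4000)
  expect_equal(es$person_days_65p, 400)
  expect_error(exposure_summary(ev, 2011, pop), "missing years")
})
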