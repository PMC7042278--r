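square_pulse_gauge <- function(years, high_days = 60, high = 400, low = 100) {
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  gauge_series(data.frame(
    date = dates, level_cm = ifelse(doy <= high_days, high, low)))
}

test_that("plot elevation is the gauge maximum minus the water mark", {
  expect_equal(plot_elevation(120, 450), 330)
  expect_equal(plot_elevation(0, 450), 450)
  expect_error(plot_elevation(500, 450), "exceeds")
  expect_error(plot_elevation(-1, 450), ">= 0")
})

test_that("flood days counts threshold exceedances of a square pulse", {
  g <- square_pulse_gauge(2001:2010, high_days = 60)
  expect_equal(as.numeric(flood_days(500, g, years = 2001:2010)), 0)
  expect_equal(as.numeric(flood_days(250, g, years = 2001:2010)), 60)
  by <- attr(flood_days(250, g, years = 2001:2010), "by_year")
  expect_true(all(by == 60))
  expect_error(flood_days(250, g, years = 1990:1999), "not covered")
})

test_that("flood duration is non-increasing in elevation", {
  set.seed(61)
  for (i in 1:20) {
    dates <- seq(as.Date("2000-01-01"), as.Date("2004-12-31"), by = "day")
    lvl <- 250 + 150 * sin(2 * pi * seq_along(dates) / 365.25) +
      rnorm(length(dates), 0, 20)
    g <- gauge_series(data.frame(date = dates, level_cm = lvl))
    elevs <- sort(runif(6, 50, 450))
    fd <- vapply(elevs, function(e)
      as.numeric(flood_days(e, g, years = 2000:2004)), numeric(1))
    expect_true(all(diff(fd) <= 0))
  }
})

test_that("short gauge gaps are interpolated, long ones rescaled", {
  g <- square_pulse_gauge(2001:2002, high_days = 60)
  # drop 3 days inside the high period: interpolation bridges them
  drop <- g$date %in% (as.Date("2001-01-10") + 0:2)
  g_small_gap <- gauge_series(as.data.frame(g)[!drop, ])
  expect_equal(as.numeric(flood_days(250, g_small_gap, years = 2001:2002)),
               60)
  # drop 30 days of the low period: denominator excludes them
  drop2 <- g$date %in% (as.Date("2001-08-01") + 0:29)
  g_big_gap <- gauge_series(as.data.frame(g)[!drop2, ])
  fd <- flood_days(250, g_big_gap, years = 2001:2002)
  expect_match(attr(fd, "gap_log"), "2001")
  expect_equal(attr(fd, "by_year")[["2001"]], 60 * 365 / 335,
               tolerance = 1e-9)
})

test_that("the flood gradient splits at its midpoint with ties going low", {
  plots <- data.frame(plot_id = paste0("P", 1:6),
                      flood_days_per_year = c(42, 60, 79, 80, 100, 117))
  sp <- split_categories(plots)
  expect_equal(sp$boundary, 79.5)
  expect_equal(sp$short$plot_ids, c("P1", "P2", "P3"))
  expect_equal(sp$long$plot_ids, c("P4", "P5", "P6"))
  expect_true(sp$boundary > 78 && sp$boundary < 80)

  two <- data.frame(plot_id = c("a", "b"), flood_days_per_year = c(10, 50))
  sp2 <- split_categories(two)
  expect_equal(sp2$short$plot_ids, "a")
  expect_equal(sp2$long$plot_ids, "b")
  # a plot exactly at the boundary goes to the lower category
  tie <- data.frame(plot_id = c("a", "b", "c"),
                    flood_days_per_year = c(10, 30, 50))
  expect_true("b" %in% split_categories(tie)$short$plot_ids)
  expect_error(split_categories(data.frame(plot_id = "a",
                                           flood_days_per_year = 5)),
               ">= 2")
  all_equal <- data.frame(plot_id = c("a", "b"),
                          flood_days_per_year = c(7, 7))
  expect_error(split_categories(all_equal), "degenerate")
})

test_that("annual minima comparison is Welch's t on before/after periods", {
  set.seed(62)
  dates <- seq(as.Date("1981-01-01"), as.Date("2015-12-31"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  lvl <- 250 + 150 * cos(2 * pi * (doy - 75) / 365.25) +
    rnorm(length(dates), 0, 5)
  drop <- (yr >= 2007) & (cos(2 * pi * (doy - 75) / 365.25) < -0.9)
  lvl[drop] <- lvl[drop] - 50
  g <- gauge_series(data.frame(date = dates, level_cm = lvl))
  ht <- annual_min_trend_test(g, breakpoint_year = 2007)
  expect_lt(ht$p.value, 0.05)
  expect_equal(as.vector(table(ht$period)), c(26L, 9L))
  # direction: the recent minima are lower
  expect_lt(mean(ht$minima[ht$period == "after"]),
            mean(ht$minima[ht$period == "before"]))
  # agrees with a direct Welch test on the same minima
  direct <- t.test(ht$minima[ht$period == "after"],
                   ht$minima[ht$period == "before"])
  expect_equal(ht$p.value, direct$p.value)

  expect_error(annual_min_trend_test(g, breakpoint_year = 2015), ">= 3")
  const <- gauge_series(data.frame(
    date = seq(as.Date("2000-01-01"), as.Date("2009-12-31"), by = "day"),
    level_cm = 200))
  expect_error(annual_min_trend_test(const, 2005), "zero variance")
})

test_that("null before/after splits reject at the nominal rate", {
  set.seed(63)
  rej <- 0
  for (i in 1:200) {
    mins <- rnorm(35, 100, 10)
    dates <- seq(as.Date("1981-06-01"), by = "year", length.out = 35)
    # build a minimal gauge with one dip per year at the planted minimum
    gd <- data.frame(
      date = sort(c(dates, dates + 90)),
      level_cm = as.vector(rbind(mins, 300)))
    g <- gauge_series(gd)
    ht <- annual_min_trend_test(g, breakpoint_year = 2007)
    rej <- rej + (ht$p.value < 0.05)
  }
  expect_gt(rej / 200, 0.01)
  expect_lt(rej / 200, 0.11)
})
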