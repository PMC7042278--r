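test_that("CBH converts to DBH by pi with the inclusion filter", {
  expect_equal(as.numeric(cbh_to_dbh(15)), 15 / pi, tolerance = 1e-12)
  expect_equal(as.numeric(cbh_to_dbh(pi * 10)), 10)
  d <- cbh_to_dbh(c(14.9, 15, 20))
  expect_true(is.na(d[1]))
  expect_equal(attr(d, "excluded"), 1L)
  expect_equal(as.numeric(cbh_to_dbh(14.9, threshold_cm = NULL)), 14.9 / pi)
})

test_that("Sturges class count rounds half up and widths partition the data", {
  set.seed(51)
  expect_equal(make_classes(runif(100, 0, 50))$K, 8L)   # 1+3.3*2 = 7.6
  expect_equal(make_classes(runif(10, 0, 50))$K, 4L)    # 4.3 -> 4
  expect_equal(make_classes(c(1, 2), k = 1)$counts, 2L)

  for (i in 1:100) {
    x <- runif(sample(5:400, 1), 0, sample(10:100, 1))
    cl <- make_classes(x)
    expect_equal(sum(cl$counts), length(x))        # partition conserves N
    expect_true(all(diff(cl$edges) > 0))
    expect_equal(cl$width * cl$K, cl$A, tolerance = 1e-9)
  }
  expect_error(make_classes(rep(3, 10)), "degenerate")
  expect_error(make_classes(5), "N >= 2")
})

test_that("class boundaries match the printed-design first class", {
  # N = 153 with breadth 8 x 11.56 starting at 5.41
  set.seed(52)
  x <- c(5.41, 5.41 + 8 * 11.56, runif(151, 5.42, 97.88))
  cl <- make_classes(x)
  expect_equal(cl$N, 153L)
  expect_equal(cl$K, 8L)
  expect_equal(cl$width, 11.56, tolerance = 1e-9)
  expect_equal(cl$edges[1], 5.41)
  expect_equal(cl$edges[2], 16.97, tolerance = 1e-9)
})

test_that("age assignment inverts the growth model and flags the asymptote", {
  fit <- c(b0 = 60, b1 = 20, b2 = 2)
  tr <- tree_records(data.frame(tree_id = c("a", "b", "c"),
                                plot_id = "P1", dbh_cm = c(30, 12, 61)))
  aged <- assign_ages(tr, fit)
  expect_equal(aged$age_yr[1:2], c(20, 10))
  expect_true(aged$age_flagged[3])
  expect_equal(aged$age_yr[3], 20)  # age of the largest invertible DBH

  # full synthetic population round-trips exactly without noise
  ages <- seq(2, 50, 0.5)
  tr2 <- tree_records(data.frame(tree_id = paste0("t", seq_along(ages)),
                                 plot_id = "P1",
                                 dbh_cm = dbh_from_age(fit, ages)))
  expect_equal(assign_ages(tr2, fit)$age_yr, ages, tolerance = 1e-9)
})

test_that("chi-square on category x class tables matches hand computation", {
  expect_equal(flood_class_chisq(rbind(c(10, 20), c(20, 10)))$statistic,
               20 / 3, tolerance = 1e-9)
  same <- rbind(c(5, 8, 12), c(5, 8, 12))
  expect_equal(flood_class_chisq(same)$statistic, 0)
  expect_equal(flood_class_chisq(same)$df, 2)

  set.seed(53)
  for (i in 1:300) {
    m <- matrix(rpois(2 * sample(2:8, 1), 20) + 5, nrow = 2)
    res <- flood_class_chisq(m, min_expected = 0)
    expect_equal(res$statistic, chisq_brute(m), tolerance = 1e-9)
    expect_equal(res$df, ncol(m) - 1)
  }
})

test_that("sparse classes pool into neighbours, reducing df", {
  m <- rbind(c(30, 25, 1, 0), c(28, 27, 0, 1))
  res <- flood_class_chisq(m)
  expect_lt(res$df, 3)
  expect_gt(length(res$pooled), 0)
  expect_equal(sum(res$table), sum(m))     # pooling conserves counts
})

test_that("environmental ANOVA separates a planted per-class shift", {
  set.seed(55)
  fit <- c(b0 = 60, b1 = 20, b2 = 2)
  ages <- rep(seq(3, 33, length.out = 30), 6)
  dbh <- dbh_from_age(fit, ages) * exp(rnorm(180, 0, 0.03))
  cl <- make_classes(dbh, fit = fit, k = 6)
  years <- 1970:2015
  dates <- seq(as.Date("1970-01-01"), as.Date("2015-12-31"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  lvl <- 250 + 150 * cos(2 * pi * (doy - 75) / 365.25) +
    rnorm(length(dates), 0, 5)
  # plant a deep trough in the establishment years of class 2
  yr_lo <- ceiling(2015 - cl$table$age_hi[2])
  yr_hi <- floor(2015 - cl$table$age_lo[2])
  sel <- yr >= yr_lo & yr <= yr_hi & cos(2 * pi * (doy - 75) / 365.25) < -0.8
  lvl[sel] <- lvl[sel] - 80
  gauge <- gauge_series(data.frame(date = dates, level_cm = lvl))
  clim <- climate_table(data.frame(
    year = rep(years, each = 12), month = rep(1:12, length(years)),
    variable = "precipitation_mm",
    value = 100 * exp(rnorm(length(years) * 12, 0, 0.2))))
  res <- climate_by_age_class(cl, clim, gauge, survey_year = 2015)
  an <- res$anova
  expect_true(an$p[an$variable == "flood_min_cm"] < 0.05)
  tk <- res$tukey$flood_min_cm
  expect_false(is.null(tk))
  lets <- tk$letters
  # class 2 carries a letter not shared with any other class
  others <- lets[-2]
  expect_false(any(strsplit(lets[2], "")[[1]] %in%
                   unlist(strsplit(others, ""))))

  # F statistic equals the brute-force variance ratio
  d <- res$data[res$data$variable == "flood_min_cm", ]
  expect_equal(an$F[an$variable == "flood_min_cm"],
               anova_f_brute(d$value, as.integer(d$class)),
               tolerance = 1e-9)
})

test_that("identical environmental histories yield one Tukey group", {
  set.seed(56)
  fit <- c(b0 = 60, b1 = 20, b2 = 2)
  ages <- rep(seq(3, 33, length.out = 30), 6)
  dbh <- dbh_from_age(fit, ages) * exp(rnorm(180, 0, 0.03))
  cl <- make_classes(dbh, fit = fit, k = 6)
  years <- 1970:2015
  dates <- seq(as.Date("1970-01-01"), as.Date("2015-12-31"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  lvl <- 250 + 150 * cos(2 * pi * (doy - 75) / 365.25) +
    rnorm(length(dates), 0, 5)
  gauge <- gauge_series(data.frame(date = dates, level_cm = lvl))
  clim <- climate_table(data.frame(
    year = rep(years, each = 12), month = rep(1:12, length(years)),
    variable = "precipitation_mm",
    value = 100 * exp(rnorm(length(years) * 12, 0, 0.2))))
  res <- climate_by_age_class(cl, clim, gauge, survey_year = 2015)
  expect_true(all(res$anova$p > 0.05))
  expect_true(all(vapply(res$tukey, is.null, logical(1))))
})
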