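test_that("glk scores parallel, opposite and tied movements as defined", {
  expect_equal(glk(c(1, 2, 3, 4), c(2, 3, 4, 5)), 100)
  expect_equal(glk(c(1, 2, 1, 2), c(2, 1, 2, 1)), 0)
  # one shared upward interval, one single-sided tie: (1 + 0.5)/2
  expect_equal(glk(c(1, 2, 2), c(1, 2, 3)), 75)
  expect_error(glk(1, 1), "aligned|overlap")
  expect_error(glk(c(1, 2), c(1, 2), min_overlap = 5), "overlap")
})

test_that("glk matches brute-force scoring on random series", {
  set.seed(11)
  for (i in 1:400) {
    n <- sample(3:40, 1)
    x <- sample(1:5, n, replace = TRUE)  # discrete levels force ties
    y <- sample(1:5, n, replace = TRUE)
    expect_equal(glk(x, y), glk_brute(x, y))
  }
})

test_that("glk is symmetric, reflexive and monotone-transform invariant", {
  set.seed(12)
  for (i in 1:50) {
    x <- rand_widths(20); y <- rand_widths(20)
    expect_equal(glk(x, x), 100)
    expect_equal(glk(x, y), glk(y, x))
    expect_equal(glk(exp(2 * x + 1), exp(2 * y + 1)), glk(x, y))
    expect_equal(glk(x^3, y^3), glk(x, y))
  }
})

test_that("t value follows the closed form in r and n", {
  set.seed(13)
  # pre-transformed pair with exact r = 0.5 by Gram-Schmidt construction
  u <- rnorm(27)
  e <- rnorm(27)
  e <- residuals(lm(e ~ u))
  su <- as.numeric(scale(u)); se <- as.numeric(scale(e))
  v <- 0.5 * su + sqrt(1 - 0.25) * se
  expect_equal(t_value_bp(su, v, transform = FALSE), 2.8867513,
               tolerance = 1e-6)
  # r = 0 gives t = 0
  expect_equal(t_value_bp(su, se, transform = FALSE), 0, tolerance = 1e-9)

  x <- rand_widths(27)
  expect_equal(t_value_bp(x, x), 100)       # capped perfect correlation
  y <- rev(x) * exp(rnorm(27, 0, 0.2))
  tv <- t_value_bp(x, y)
  r <- cor(log(x / ma5_brute(x)), log(y / ma5_brute(y)))
  expect_equal(tv, r * sqrt(25 / (1 - r^2)), tolerance = 1e-10)
  expect_error(t_value_bp(x[1:3], y[1:3]), ">= 4")
  expect_error(t_value_bp(rep(2, 10), x[1:10]), "zero variance")
})

test_that("t value equals the brute-force transform-then-correlate oracle", {
  set.seed(14)
  for (i in 1:400) {
    n <- sample(6:40, 1)
    x <- rand_widths(n); y <- rand_widths(n)
    expect_equal(t_value_bp(x, y), tbp_brute(x, y), tolerance = 1e-9)
  }
})

test_that("best_lag recovers planted shifts and is antisymmetric", {
  set.seed(15)
  w <- rand_widths(30)
  x <- ring_series("X", first_year = 1980, widths = w)
  y3 <- ring_series("Y", first_year = 1980, widths = w[4:30])  # truly 1983
  r <- best_lag(x, y3, max_shift = 5)
  expect_equal(r$lag, 3)
  expect_equal(r$report$glk, 100)
  expect_true(r$report$admitted)

  expect_equal(best_lag(x, x, max_shift = 5)$lag, 0)
  # antisymmetry on a noiseless shift
  expect_equal(best_lag(y3, x, max_shift = 5)$lag, -3)

  # planted offset with 10% noise still recovered
  set.seed(16)
  for (i in 1:10) {
    w <- rand_widths(40)
    off <- sample(-4:4, 1)
    a <- ring_series("A", first_year = 1950, widths = w)
    b <- ring_series("B", first_year = 1950 - off,
                     widths = w * exp(rnorm(40, 0, 0.1)))
    expect_equal(best_lag(a, b, max_shift = 6)$lag, off)
  }
  short <- ring_series("S", first_year = 1700, widths = rand_widths(8))
  expect_error(best_lag(x, short, max_shift = 2), "overlap")
})

test_that("missing inner rings estimated from inner mean width", {
  s <- ring_series("A", first_year = 2000, widths = c(2, 2, 2, 2, 2, 4))
  expect_equal(estimate_missing_rings(s, 10), 5L)
  expect_equal(estimate_missing_rings(s, 0), 0L)
  s2 <- ring_series("B", first_year = 2000, widths = c(1, 2, 3, 2, 2, 9))
  expect_equal(estimate_missing_rings(s2, 7), 4L)  # round(7/2)
  expect_error(estimate_missing_rings(s, -1), "negative")
})

test_that("coherent series are admitted and pure noise is rejected", {
  series <- make_signal_series(10, 34, signal_sd = 0.4, noise_sd = 0.1,
                               seed = 17)
  res <- crossdate_set(series)
  expect_length(res$admitted, 10L)
  expect_length(res$rejected, 0L)

  set.seed(18)
  noise <- ring_series("NOISE", first_year = 1981,
                       widths = 2 * exp(rnorm(34, 0, 0.4)))
  res2 <- crossdate_set(c(series[1:9], list(noise)))
  expect_equal(res2$rejected, "NOISE")
  expect_length(res2$admitted, 9L)
  expect_false(res2$report$admitted[res2$report$series_id == "NOISE"])

  # two identical series: both admitted with perfect agreement
  twins <- list(series[[1]],
                ring_series("S99", first_year = series[[1]]$first_year,
                            widths = series[[1]]$widths))
  res3 <- crossdate_set(twins)
  expect_length(res3$admitted, 2L)
  expect_equal(res3$report$glk, c(100, 100))
})
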