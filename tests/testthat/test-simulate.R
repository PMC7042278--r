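test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config()
  c1 <- simulate_climate(cfg, seed = 5)
  c2 <- simulate_climate(cfg, seed = 5)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  g1 <- simulate_gauge(cfg, seed = 5)
  expect_identical(g1, simulate_gauge(cfg, seed = 5))
  r1 <- simulate_ring_series(cfg, c1, seed = 5)
  r2 <- simulate_ring_series(cfg, c1, seed = 5)
  expect_identical(r1[], r2[])
  p1 <- simulate_population(cfg, seed = 5)
  expect_identical(p1, simulate_population(cfg, seed = 5))
})

test_that("zero precipitation noise reproduces the seasonal profile", {
  cfg <- sim_config(precip_sdlog = 0, precip_enso_coupling = 0)
  clim <- simulate_climate(cfg, seed = 6)
  pm <- climate_matrix(clim, "precipitation_mm")
  for (yr in seq_len(nrow(pm)))
    expect_equal(unname(pm[yr, ]), cfg$precip_seasonal)
})

test_that("uncoupled precipitation is independent of the ENSO state", {
  cfg <- sim_config(precip_enso_coupling = 0)
  set.seed(7)
  clim <- simulate_climate(cfg)
  pm <- climate_matrix(clim, "precipitation_mm")
  latent <- attr(clim, "latent_enso")
  r <- cor(as.vector(log(pm)), as.vector(latent))
  expect_lt(abs(r), 0.1)

  # with coupling on, warm months are drier
  set.seed(7)
  clim2 <- simulate_climate(sim_config(precip_enso_coupling = 0.3))
  pm2 <- climate_matrix(clim2, "precipitation_mm")
  r2 <- cor(as.vector(log(pm2)), as.vector(attr(clim2, "latent_enso")))
  expect_lt(r2, -0.2)
})

test_that("a noise-free gauge matches the analytic days-above count", {
  cfg <- sim_config(gauge_noise_sd = 0, gauge_amp_sdlog = 0,
                    min_decline_cm = 0)
  g <- simulate_gauge(cfg, seed = 8)
  # closed form for a sinusoid: fraction of the year above level e is
  # acos((e - base)/amp)/pi
  for (e in c(300, 350, 390)) {
    analytic <- 365.25 * acos((e - cfg$gauge_base_cm) / cfg$gauge_amp_cm) / pi
    measured <- as.numeric(flood_days(e, g, years = 1990:1999))
    expect_equal(measured, analytic, tolerance = 0.05)
  }
  # amplitude zero collapses to a constant level
  flat <- simulate_gauge(sim_config(gauge_amp_cm = 0, gauge_noise_sd = 0,
                                    gauge_amp_sdlog = 0,
                                    min_decline_cm = 0), seed = 8)
  expect_equal(diff(range(flat$level_cm)), 0)
})

test_that("the planted trough decline lowers minima but not maxima", {
  cfg <- sim_config(gauge_noise_sd = 0, gauge_amp_sdlog = 0)
  g <- simulate_gauge(cfg, seed = 9)
  yr <- as.integer(format(g$date, "%Y"))
  mins <- tapply(g$level_cm, yr, min)
  maxs <- tapply(g$level_cm, yr, max)
  before <- as.integer(names(mins)) < cfg$survey_year - cfg$decline_years + 1L
  expect_equal(mean(mins[!before]) - mean(mins[before]), -cfg$min_decline_cm,
               tolerance = 1)
  expect_lt(abs(mean(maxs[!before]) - mean(maxs[before])), 10)
  ht <- annual_min_trend_test(simulate_gauge(sim_config(), seed = 9),
                              cfg$survey_year - cfg$decline_years + 1L)
  expect_lt(ht$p.value, 0.05)
})

test_that("effect-free ring series follow the deterministic age trend", {
  cfg <- sim_config(b_precip = 1e-9, b_enso = -1e-9, ring_noise_sd = 0,
                    common_noise_sd = 0)
  clim <- simulate_climate(cfg, seed = 10)
  rings <- simulate_ring_series(cfg, clim, seed = 10)
  s <- rings[[1]]
  ages <- seq_along(s$widths)
  # analytic derivative-based increments, to bench rounding
  p <- cfg$growth
  u <- (p[["b1"]] / ages)^p[["b2"]]
  expected_mm <- round(p[["b0"]] * p[["b2"]] * u / (ages * (1 + u)^2) * 5, 2)
  expect_equal(s$widths, pmax(expected_mm, 0.01))
})

test_that("the population respects the inclusion threshold and flood design", {
  cfg <- sim_config()
  pop <- simulate_population(cfg, seed = 11)
  expect_equal(nrow(pop$trees), cfg$n_trees_population)
  expect_equal(nrow(pop$plots), cfg$n_plots)
  expect_true(all(pop$trees$dbh_cm >= cfg$cbh_threshold_cm / pi))
  expect_true(all(pop$plots$water_mark_cm >= 0))
  # the deficit: no young trees in short-flood plots under the default
  cat_of <- setNames(pop$plots$category, pop$plots$plot_id)
  young <- pop$trees$age_yr_true < cfg$decline_years
  expect_equal(sum(young & cat_of[pop$trees$plot_id] == "short"), 0L)
  expect_gt(sum(young & cat_of[pop$trees$plot_id] == "long"), 0L)
  # no deficit restores young recruitment in both categories
  pop2 <- simulate_population(sim_config(recruit_decline = 1), seed = 11)
  young2 <- pop2$trees$age_yr_true < cfg$decline_years
  expect_gt(sum(young2 & cat_of[pop2$trees$plot_id] == "short"), 0L)
})

test_that("simulated flood durations span the configured gradient", {
  cfg <- sim_config()
  sim <- simulate_study(cfg, seed = 12)
  fd <- vapply(sim$plots$elevation_cm, function(e)
    as.numeric(flood_days(e, sim$gauge,
                          years = (cfg$survey_year - 9):cfg$survey_year)),
    numeric(1))
  expect_gt(min(fd), 20)
  expect_lt(max(fd), 140)
  expect_gt(max(fd) - min(fd), 40)   # a real gradient, short to long
  # lower plots flood longer
  expect_true(all(diff(fd[order(sim$plots$elevation_cm)]) <= 0))
})
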