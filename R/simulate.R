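#' Configuration of a synthetic dendroecological study
#'
#' Bundles every parameter of the synthetic study generator. The
#' defaults describe a 34-year (1981--2014) chronology of 36 trees with
#' a positive December(-1) precipitation signal and a negative ENSO
#' signal, a 153-tree inventory in 24 plots of 50 x 5 m (0.6 ha)
#' spanning a 42--117 days/yr flood gradient, a monomodal annual flood
#' pulse, and a recruitment deficit in the final nine years confined to
#' the shorter-flooded plots.
#'
#' @param n_years Chronology span in years (default 34).
#' @param last_year Last ring year (default 2014; the inventory and the
#'   flood marks date from `last_year + 1`).
#' @param n_trees_chronology Trees in the ring-width sample (default 36,
#'   of which `n_destructive` are stem discs).
#' @param n_destructive Destructive (disc) samples (default 7).
#' @param n_trees_population Inventoried trees (default 153).
#' @param n_plots Inventory plots (default 24).
#' @param plot_area_m2 Plot area (default 250, a 50 x 5 m plot).
#' @param growth Named vector `b0, b1, b2` of the sigmoidal age--diameter
#'   truth (defaults 84 cm, 33.5 yr, 1.3: an increment peak of
#'   ~1.6 cm/yr at ~7 yr).
#' @param height Named vector `a, b` of the diameter--height truth
#'   (defaults 28 m, 15 cm).
#' @param height_noise_sd Height measurement noise, m (default 1.5).
#' @param b_precip Log-scale ring-width effect per SD of December(-1)
#'   log precipitation (> 0; default 0.12).
#' @param b_enso Log-scale effect per SD of the Dec(-1)--Feb ENSO state
#'   (< 0; default -0.15).
#' @param b_flood Log-scale effect per SD of growth-year mean river
#'   level (default 0: the flood pulse does not drive ring width).
#' @param ring_noise_sd Per-tree lognormal ring noise (default 0.30).
#' @param common_noise_sd Stand-level lognormal noise shared by all
#'   trees, AR(1) 0.3 (default 0.15) — non-climatic common variance.
#' @param enso_ar1 AR(1) coefficient of the monthly latent ENSO state
#'   (default 0.9, unit stationary variance).
#' @param precip_seasonal Monthly mean precipitation profile, mm
#'   (default a Pantanal-like ~1240 mm/yr profile peaking Nov--Mar).
#' @param precip_sdlog Lognormal monthly precipitation noise
#'   (default 0.30).
#' @param precip_enso_coupling Fractional precipitation reduction per
#'   unit positive ENSO anomaly (default 0.10: warm events are dry).
#' @param gauge_base_cm,gauge_amp_cm Level and amplitude of the annual
#'   sinusoidal flood pulse, cm (defaults 250 and 150).
#' @param gauge_peak_doy Day of year of the flood peak (default 75,
#'   mid-March).
#' @param gauge_noise_sd,gauge_noise_ar1 Daily AR(1) gauge noise
#'   (defaults 8 cm, 0.8).
#' @param gauge_amp_sdlog Year-to-year lognormal variation of the pulse
#'   amplitude (default 0.05).
#' @param min_decline_cm Lowering of the dry-season trough in the final
#'   `decline_years` (default 40 cm; 0 disables the trend).
#' @param decline_years Length of the final period carrying the trough
#'   decline and the recruitment deficit (default 9).
#' @param flood_days_range Target flood-duration gradient across plots,
#'   days/yr (default `c(42, 117)`).
#' @param age_range_chronology Ages of the ring-width sample at
#'   `last_year` (default `c(6, 34)`; the oldest is always present so
#'   the chronology spans exactly `n_years`).
#' @param pop_age_range Inventory age range (default `c(4, 54)`).
#' @param pop_age_meanlog,pop_age_sdlog Lognormal recruitment-age
#'   profile (defaults `log(13)`, 0.70: a young stand, most trees under
#'   about 22 years).
#' @param recruit_decline Recruitment multiplier for trees younger than
#'   `decline_years` in the short-flood plots (default 0: recruitment in
#'   those plots stops during the final period; 1 disables the deficit).
#' @param long_flood_weight Relative tree density of longer-flooded
#'   plots (default 1.5, giving roughly the 62/91 split of the two
#'   categories).
#' @param dbh_noise_sdlog Lognormal DBH noise around the growth curve
#'   (default 0.10); draws below the 15-cm CBH inclusion threshold are
#'   redrawn (truncation).
#' @param bark_factor Field DBH over cumulative ring-sum DBH for the
#'   ring-width sample (default 1.08: bark plus off-centre bias).
#' @param cbh_threshold_cm Inclusion threshold (default 15).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_years = 34L, last_year = 2014L,
                       n_trees_chronology = 36L, n_destructive = 7L,
                       n_trees_population = 153L, n_plots = 24L,
                       plot_area_m2 = 250,
                       growth = c(b0 = 84, b1 = 33.5, b2 = 1.3),
                       height = c(a = 28, b = 15), height_noise_sd = 1.5,
                       b_precip = 0.12, b_enso = -0.15, b_flood = 0,
                       ring_noise_sd = 0.30, common_noise_sd = 0.15,
                       enso_ar1 = 0.9,
                       precip_seasonal = c(210, 190, 160, 90, 40, 15,
                                           8, 12, 45, 110, 160, 200),
                       precip_sdlog = 0.30, precip_enso_coupling = 0.10,
                       gauge_base_cm = 250, gauge_amp_cm = 150,
                       gauge_peak_doy = 75L, gauge_noise_sd = 8,
                       gauge_noise_ar1 = 0.8, gauge_amp_sdlog = 0.05,
                       min_decline_cm = 40, decline_years = 9L,
                       flood_days_range = c(42, 117),
                       age_range_chronology = c(6L, 34L),
                       pop_age_range = c(4L, 54L),
                       pop_age_meanlog = log(13), pop_age_sdlog = 0.70,
                       recruit_decline = 0, long_flood_weight = 1.5,
                       dbh_noise_sdlog = 0.10, bark_factor = 1.08,
                       cbh_threshold_cm = 15) {
  stopifnot(n_years >= 10L, b_precip > 0, b_enso < 0,
            ring_noise_sd >= 0, common_noise_sd >= 0, precip_sdlog >= 0,
            gauge_noise_sd >= 0, length(precip_seasonal) == 12L,
            recruit_decline >= 0, recruit_decline <= 1)
  cfg <- as.list(environment())
  cfg$first_year <- last_year - n_years + 1L
  cfg$survey_year <- last_year + 1L
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> chronology %d-%d (%d trees), population %d trees / %d plots\n",
    x$first_year, x$last_year, x$n_trees_chronology,
    x$n_trees_population, x$n_plots))
  invisible(x)
}

ar1_series <- function(n, phi, sd_stationary = 1) {
  if (n == 0L) return(numeric())
  innov_sd <- sd_stationary * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1L] <- stats::rnorm(1, 0, sd_stationary)
  for (i in seq_len(n - 1L))
    x[i + 1L] <- phi * x[i] + stats::rnorm(1, 0, innov_sd)
  x
}

#' Simulate monthly climate and ENSO indices
#'
#' Monthly Nino SST anomaly indices (1+2, 3, 3.4, 4) are correlated
#' projections of one latent AR(1) ENSO state (unit variance); SOI is
#' its negative correlate and PDO an independent slow AR(1).
#' Precipitation is the seasonal profile times lognormal noise times
#' `1 - coupling * max(latent, 0)`, so warm (El Nino) months are dry.
#' The table covers `first_year - 1` through `last_year + 1` so that
#' lagged-window correlation screens have full coverage.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional RNG seed.
#' @return A [climate_table()] with the latent monthly ENSO state
#'   attached as attribute `"latent_enso"` (a year x 12 matrix).
#' @export
simulate_climate <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  yrs <- (cfg$first_year - 1L):(cfg$last_year + 1L)
  nm <- length(yrs) * 12L
  latent <- ar1_series(nm, cfg$enso_ar1)
  proj <- function(load) load * latent + sqrt(1 - load^2) * stats::rnorm(nm)
  nino12 <- proj(0.95); nino3 <- proj(0.95)
  nino34 <- proj(0.90); nino4 <- proj(0.85)
  soi <- -proj(0.80)
  pdo <- ar1_series(nm, 0.95)
  precip <- rep(cfg$precip_seasonal, times = length(yrs)) *
    exp(stats::rnorm(nm, 0, cfg$precip_sdlog)) *
    pmax(1 - cfg$precip_enso_coupling * pmax(latent, 0), 0.05)
  long <- function(v, val) data.frame(
    year = rep(yrs, each = 12L), month = rep(1:12, length(yrs)),
    variable = v, value = val)
  tab <- climate_table(rbind(
    long("precipitation_mm", precip),
    long("nino12", nino12), long("nino3", nino3),
    long("nino34", nino34), long("nino4", nino4),
    long("soi", soi), long("pdo", pdo)))
  attr(tab, "latent_enso") <- matrix(latent, nrow = length(yrs), ncol = 12L,
                                     byrow = TRUE, dimnames = list(yrs, NULL))
  tab
}

#' Simulate a daily river-gauge record
#'
#' A monomodal sinusoidal flood pulse with year-to-year amplitude
#' variation and daily AR(1) noise. When `min_decline_cm > 0`, the final
#' `decline_years` (ending at the survey year) have their dry-season
#' trough lowered by that amount, leaving the peak unchanged — a
#' decline in annual minima without a decline in maxima. The survey
#' year's amplitude is kept at least nominal so that flood marks sit
#' below the annual maximum.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional RNG seed.
#' @return A [gauge_series()] covering `first_year` Jan 1 through
#'   `survey_year` Dec 31.
#' @export
simulate_gauge <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(as.Date(paste0(cfg$first_year, "-01-01")),
               as.Date(paste0(cfg$survey_year, "-12-31")), by = "day")
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  yrs <- unique(yr)
  amp_mult <- stats::setNames(exp(stats::rnorm(length(yrs), 0,
                                               cfg$gauge_amp_sdlog)), yrs)
  amp_mult[as.character(cfg$survey_year)] <-
    max(amp_mult[as.character(cfg$survey_year)], 1.05)
  phase <- cos(2 * pi * (doy - cfg$gauge_peak_doy) / 365.25)
  level <- cfg$gauge_base_cm +
    cfg$gauge_amp_cm * amp_mult[as.character(yr)] * phase
  decline_from <- cfg$survey_year - cfg$decline_years + 1L
  sel <- yr >= decline_from & phase < 0
  level[sel] <- level[sel] + cfg$min_decline_cm * phase[sel]
  level <- level + ar1_series(length(level), cfg$gauge_noise_ar1,
                              cfg$gauge_noise_sd)
  gauge_series(data.frame(date = dates, level_cm = level))
}

#' Monthly mean gauge levels as climate-table rows
#'
#' @param gauge A [gauge_series()].
#' @return Data frame in long climate schema with variable
#'   `gauge_level_cm`, suitable for [rbind()]ing into a climate table.
#' @export
gauge_monthly_means <- function(gauge) {
  stopifnot(inherits(gauge, "gauge_series"))
  yr <- as.integer(format(gauge$date, "%Y"))
  mo <- as.integer(format(gauge$date, "%m"))
  agg <- stats::aggregate(gauge$level_cm, list(year = yr, month = mo), mean)
  data.frame(year = agg$year, month = agg$month,
             variable = "gauge_level_cm", value = agg$x)
}

# Standardized December(t-1) log precipitation, seasonal (Dec(t-1)-Feb)
# latent ENSO state and growth-year (Oct(t-1)-Sep) mean gauge level for
# each requested ring year.
ring_year_drivers <- function(climate, ring_years) {
  pm <- climate_matrix(climate, "precipitation_mm")
  cyrs <- as.integer(rownames(pm))
  zp <- as.numeric(scale(log(pm[match(ring_years - 1L, cyrs), 12L])))
  latent <- attr(climate, "latent_enso")
  if (is.null(latent)) latent <- climate_matrix(climate, "nino34")
  lyrs <- as.integer(rownames(latent))
  ze <- (latent[match(ring_years - 1L, lyrs), 12L] +
         latent[match(ring_years, lyrs), 1L] +
         latent[match(ring_years, lyrs), 2L]) / 3
  ze <- as.numeric(scale(ze))
  zf <- NULL
  if ("gauge_level_cm" %in% unique(climate$variable)) {
    gm <- climate_matrix(climate, "gauge_level_cm")
    gyrs <- as.integer(rownames(gm))
    ann <- rowMeans(gm[match(ring_years, gyrs), , drop = FALSE])
    zf <- as.numeric(scale(ann))
  }
  list(z_precip = zp, z_enso = ze, z_flood = zf)
}

#' Simulate a cross-datable set of ring-width series
#'
#' Each tree germinates so that its age at `last_year` lies in
#' `age_range_chronology` (the oldest age always present, so the set
#' spans exactly `n_years`). The expected radial width in year t is the
#' growth model's annual increment at the tree's age, times
#' `exp(b_precip z_precip + b_enso z_enso + b_flood z_flood)` with the
#' drivers taken from the supplied climate, times shared stand-level
#' AR(1) lognormal noise, times per-tree lognormal noise.
#'
#' @param cfg A [sim_config()].
#' @param climate A [simulate_climate()] table (a merged gauge variable
#'   is used only when `b_flood != 0`).
#' @param seed Optional RNG seed.
#' @return Named list of [ring_series()]; per-tree field DBH (cm,
#'   cumulative diameter times `bark_factor`) in attribute
#'   `"field_dbh_cm"`, the planted drivers in attribute `"drivers"`.
#' @export
simulate_ring_series <- function(cfg, climate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_trees_chronology
  ages <- sample(seq(cfg$age_range_chronology[1L],
                     cfg$age_range_chronology[2L]), n, replace = TRUE)
  ages[1L] <- cfg$age_range_chronology[2L]  # anchor the full span
  ring_years <- cfg$first_year:cfg$last_year
  drv <- ring_year_drivers(climate, ring_years)
  climate_term <- cfg$b_precip * drv$z_precip + cfg$b_enso * drv$z_enso
  if (cfg$b_flood != 0) {
    if (is.null(drv$z_flood))
      stop("simulate_ring_series: b_flood != 0 needs a gauge_level_cm variable",
           call. = FALSE)
    climate_term <- climate_term + cfg$b_flood * drv$z_flood
  }
  common <- ar1_series(length(ring_years), 0.3, cfg$common_noise_sd)
  p <- cfg$growth
  increment_cm <- function(age) {
    u <- (p[["b1"]] / age)^p[["b2"]]
    p[["b0"]] * p[["b2"]] * u / (age * (1 + u)^2)
  }
  out <- vector("list", n)
  field_dbh <- numeric(n)
  for (i in seq_len(n)) {
    germ <- cfg$last_year - ages[i] + 1L
    yrs_i <- germ:cfg$last_year
    a <- seq_along(yrs_i)
    k <- match(yrs_i, ring_years)
    mu <- increment_cm(a) * 5 *      # cm diameter/yr -> mm radius/yr
      exp(climate_term[k] + common[k])
    w <- mu * exp(stats::rnorm(length(a), 0, cfg$ring_noise_sd))
    w <- pmax(round(w, 2), 0.01)     # bench resolution, strictly positive
    id <- sprintf("EF%02d%s", i,
                  if (i <= cfg$n_destructive) "D" else "C")
    out[[i]] <- ring_series(id, tree_id = sprintf("tree%02d", i),
                            first_year = germ, widths = w,
                            method = if (i <= cfg$n_destructive)
                              "destructive" else "core")
    field_dbh[i] <- 2 * sum(w) / 10 * cfg$bark_factor
  }
  names(out) <- vapply(out, `[[`, "", "series_id")
  names(field_dbh) <- names(out)
  attr(out, "field_dbh_cm") <- field_dbh
  attr(out, "drivers") <- drv
  out
}

#' Simulate the plot inventory and tree population
#'
#' Plot elevations are spaced evenly across the elevation band whose
#' sinusoidal days-above-threshold equal `flood_days_range`; water marks
#' are the survey-year gauge maximum minus the elevation. Tree ages are
#' drawn from a lognormal recruitment profile over `pop_age_range`, with
#' recruitment in the final `decline_years` multiplied by
#' `recruit_decline` in the shorter-flooded half of the plots; DBH is
#' the growth curve at that age times lognormal noise, redrawn while
#' below the CBH inclusion threshold; heights follow the saturating
#' diameter--height truth plus Gaussian noise.
#'
#' @param cfg A [sim_config()].
#' @param gauge A [simulate_gauge()] series (for the survey-year
#'   maximum); `NULL` uses the nominal pulse peak.
#' @param seed Optional RNG seed.
#' @return List with `trees` ([tree_records()] including true `age_yr`),
#'   `plots` ([plot_records()] including true `elevation_cm` and
#'   `category`).
#' @export
simulate_population <- function(cfg, gauge = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # invert the sinusoid: a plot flooded d days/yr sits at relative level
  # cos(pi d / 365.25); elevations evenly spaced between the two targets
  x <- cos(pi * cfg$flood_days_range / 365.25)
  elev <- cfg$gauge_base_cm +
    cfg$gauge_amp_cm * seq(x[1L], x[2L], length.out = cfg$n_plots)
  survey_max <- if (!is.null(gauge)) {
    yr <- as.integer(format(gauge$date, "%Y"))
    max(gauge$level_cm[yr == cfg$survey_year])
  } else cfg$gauge_base_cm + 1.05 * cfg$gauge_amp_cm
  plots <- plot_records(data.frame(
    plot_id = sprintf("P%02d", seq_len(cfg$n_plots)),
    area_m2 = cfg$plot_area_m2,
    water_mark_cm = pmax(survey_max - elev, 0)))
  plots$elevation_cm <- elev
  # longer-flooded = lower elevation = first half of the gradient
  plots$category <- ifelse(elev <= stats::median(elev), "long", "short")

  ages_all <- cfg$pop_age_range[1L]:cfg$pop_age_range[2L]
  age_w <- stats::dlnorm(ages_all, cfg$pop_age_meanlog, cfg$pop_age_sdlog)
  plot_w <- ifelse(plots$category == "long", cfg$long_flood_weight, 1)
  joint <- outer(plot_w, age_w)
  young <- ages_all < cfg$decline_years
  joint[plots$category == "short", young] <-
    joint[plots$category == "short", young] * cfg$recruit_decline
  pick <- sample(length(joint), cfg$n_trees_population, replace = TRUE,
                 prob = as.vector(joint))
  plot_i <- (pick - 1L) %% nrow(joint) + 1L
  age <- ages_all[(pick - 1L) %/% nrow(joint) + 1L]

  thr_dbh <- cfg$cbh_threshold_cm / pi
  mu_dbh <- dbh_from_age(cfg$growth, age)
  dbh <- mu_dbh * exp(stats::rnorm(length(age), 0, cfg$dbh_noise_sdlog))
  while (any(dbh < thr_dbh)) {   # truncated below the inclusion threshold
    i <- which(dbh < thr_dbh)
    dbh[i] <- mu_dbh[i] * exp(stats::rnorm(length(i), 0, cfg$dbh_noise_sdlog))
  }
  h <- cfg$height[["a"]] * dbh / (cfg$height[["b"]] + dbh) +
    stats::rnorm(length(dbh), 0, cfg$height_noise_sd)
  h <- pmax(h, 1.3)
  trees <- tree_records(data.frame(
    tree_id = sprintf("T%03d", seq_along(dbh)),
    plot_id = plots$plot_id[plot_i],
    cbh_cm = dbh * pi, dbh_cm = dbh, height_m = h))
  trees$age_yr_true <- age
  list(trees = trees, plots = plots)
}

#' Simulate a complete synthetic study
#'
#' Runs all generators under one seed and returns every input the
#' analysis pipeline needs, along with the planted ground truth.
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed (default 42).
#' @return List: `config`, `climate` (including monthly mean gauge
#'   level as `gauge_level_cm`), `gauge`, `rings`, `field_dbh_cm`,
#'   `trees`, `plots`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 42L) {
  set.seed(seed)
  climate <- simulate_climate(cfg)
  gauge <- simulate_gauge(cfg)
  latent <- attr(climate, "latent_enso")
  climate <- climate_table(rbind(as.data.frame(climate),
                                 gauge_monthly_means(gauge)))
  attr(climate, "latent_enso") <- latent
  rings <- simulate_ring_series(cfg, climate)
  pop <- simulate_population(cfg, gauge)
  list(config = cfg, climate = climate, gauge = gauge, rings = rings,
       field_dbh_cm = attr(rings, "field_dbh_cm"),
       trees = pop$trees, plots = pop$plots, seed = seed)
}
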