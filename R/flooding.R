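#' Plot elevation on the gauge datum
#'
#' Flood-pulse floodplains near a gauge can be treated as hydraulically
#' flat: the water surface at the plot tracks the gauge. The elevation
#' of the plot ground above gauge zero is then the year's maximum gauge
#' level minus the water mark the flood left on the trees:
#' `elevation = gauge_annual_max - water_mark`.
#'
#' @param water_mark_cm Mean flood-mark height above ground, cm (>= 0).
#' @param gauge_annual_max_cm Highest gauge level recorded in the year
#'   the mark was left, cm (>= water mark).
#' @return Elevation in cm on the gauge datum.
#' @examples
#' plot_elevation(120, 450)  # 330
#' @export
plot_elevation <- function(water_mark_cm, gauge_annual_max_cm) {
  if (any(water_mark_cm < 0) || any(gauge_annual_max_cm < 0))
    stop("plot_elevation: inputs must be >= 0", call. = FALSE)
  if (any(water_mark_cm > gauge_annual_max_cm))
    stop("plot_elevation: water mark exceeds the annual gauge maximum",
         call. = FALSE)
  gauge_annual_max_cm - water_mark_cm
}

#' Mean annual flood duration at an elevation
#'
#' Counts, for each calendar year of the window, the days on which the
#' gauge level exceeds the plot elevation, and returns the mean across
#' years. Gaps in the gauge record of up to `max_gap` days are filled by
#' linear interpolation; years with longer gaps have their flooded-day
#' count rescaled from observed days to the full year (the unobserved
#' days are excluded from the denominator), and the handling is logged
#' in the attached attribute.
#'
#' @param elevation_cm Elevation on the gauge datum, cm.
#' @param gauge A [gauge_series()].
#' @param years Integer vector of calendar years to average over
#'   (default: the last 10 complete years in the record).
#' @param max_gap Longest gap filled by interpolation (default 5 days).
#' @return Mean days per year flooded, with attribute `"by_year"` (per
#'   year counts) and `"gap_log"`.
#' @export
flood_days <- function(elevation_cm, gauge, years = NULL, max_gap = 5L) {
  stopifnot(inherits(gauge, "gauge_series"))
  all_days <- seq(min(gauge$date), max(gauge$date), by = "day")
  lvl <- rep(NA_real_, length(all_days))
  lvl[match(gauge$date, all_days)] <- gauge$level_cm
  lvl <- zoo::na.approx(lvl, maxgap = max_gap, na.rm = FALSE)
  yr <- as.integer(format(all_days, "%Y"))
  if (is.null(years)) {
    full <- as.integer(names(which(table(yr) >= 365)))
    years <- utils::tail(sort(full), 10L)
  }
  if (!all(years %in% yr))
    stop("flood_days: requested years not covered by the gauge record",
         call. = FALSE)
  gap_log <- character()
  by_year <- vapply(years, function(y) {
    v <- lvl[yr == y]
    n_na <- sum(is.na(v))
    if (n_na > 0) {
      gap_log <<- c(gap_log, sprintf(
        "%d: %d unobserved day(s) excluded from the denominator", y, n_na))
    }
    obs <- sum(!is.na(v))
    if (obs == 0L) return(NA_real_)
    sum(v > elevation_cm, na.rm = TRUE) * length(v) / obs
  }, numeric(1))
  out <- mean(by_year, na.rm = TRUE)
  attr(out, "by_year") <- stats::setNames(by_year, years)
  attr(out, "gap_log") <- gap_log
  out
}

#' Split plots into two flood-duration categories
#'
#' The inundation gradient `[min, max]` of the observed per-plot flood
#' durations is halved at its midpoint; plots at or below the boundary
#' form the shorter-flooded category (ties go to the lower category).
#'
#' @param plots A [plot_records()] data frame with a `flood_days_per_year`
#'   column (or any data frame with `plot_id` and that column).
#' @return List of two elements (`short`, `long`), each with `label`
#'   (day range), `boundary`, `plot_ids`, `flood_days`; plus the
#'   `boundary` value itself.
#' @export
split_categories <- function(plots) {
  fd <- plots$flood_days_per_year
  if (is.null(fd)) stop("split_categories: flood_days_per_year required",
                        call. = FALSE)
  if (length(fd) < 2L) stop("split_categories: need >= 2 plots", call. = FALSE)
  lo <- min(fd); hi <- max(fd)
  if (lo == hi)
    stop("split_categories: degenerate gradient (all plots equal)",
         call. = FALSE)
  boundary <- (lo + hi) / 2
  short <- fd <= boundary
  cat_of <- function(sel) list(
    label = sprintf("%.0f-%.0f days/yr", min(fd[sel]), max(fd[sel])),
    plot_ids = plots$plot_id[sel],
    flood_days = fd[sel])
  list(short = cat_of(short), long = cat_of(!short), boundary = boundary)
}

#' Before/after comparison of annual minimum gauge levels
#'
#' Welch's two-sided two-sample t-test of the annual minimum water
#' levels before versus after a breakpoint year — the screen for a
#' recent decline in dry-season minima. The breakpoint year itself
#' belongs to the "after" period.
#'
#' @param gauge A [gauge_series()].
#' @param breakpoint_year First year of the "after" period.
#' @param years Optional restriction of the years used.
#' @return `htest` object from [stats::t.test()], augmented with
#'   `minima` (named per-year minima) and `period` factors.
#' @export
annual_min_trend_test <- function(gauge, breakpoint_year, years = NULL) {
  stopifnot(inherits(gauge, "gauge_series"))
  yr <- as.integer(format(gauge$date, "%Y"))
  mins <- tapply(gauge$level_cm, yr, min)
  use <- as.integer(names(mins))
  if (!is.null(years)) {
    mins <- mins[as.character(years[years %in% use])]
    use <- as.integer(names(mins))
  }
  after <- use >= breakpoint_year
  if (sum(after) < 3L || sum(!after) < 3L)
    stop("annual_min_trend_test: need >= 3 years on each side of the breakpoint",
         call. = FALSE)
  if (stats::sd(mins[after]) == 0 && stats::sd(mins[!after]) == 0)
    stop("annual_min_trend_test: zero variance in both periods", call. = FALSE)
  ht <- stats::t.test(mins[after], mins[!after], var.equal = FALSE)
  ht$minima <- mins
  ht$period <- factor(ifelse(after, "after", "before"),
                      levels = c("before", "after"))
  ht
}
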