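#' Construct a dated ring-width series
#'
#' A `ring_series` holds one tree's dated annual radial increments in mm,
#' ordered oldest to youngest, at 0.01 mm resolution. The calendar
#' convention used throughout the package is that a ring is labelled by
#' the calendar year in which its growth season starts (the season starts
#' in October; the new wood layer forms around December--January).
#'
#' @param series_id Character scalar, measurement series identifier
#'   (at most 8 characters for Tucson/RWL round trips).
#' @param tree_id Character scalar, the tree the series belongs to.
#'   Defaults to `series_id`.
#' @param first_year Integer, calendar year of the innermost measured ring.
#' @param widths Numeric vector of radial increments in mm; all must be
#'   strictly positive.
#' @param pith_offset Non-negative integer count of unmeasured inner
#'   rings (cores that missed the pith); default 0.
#' @param method `"destructive"` (stem disc) or `"core"` (increment borer).
#'
#' @return An object of class `"ring_series"`: a list with fields
#'   `series_id`, `tree_id`, `first_year`, `widths`, `pith_offset`,
#'   `method`, and derived `last_year`.
#' @examples
#' rs <- ring_series("T01", first_year = 1990, widths = c(1.2, 0.8, 1.5))
#' rs$last_year  # 1992
#' @export
ring_series <- function(series_id, tree_id = series_id, first_year, widths,
                        pith_offset = 0L, method = c("core", "destructive")) {
  method <- match.arg(method)
  stopifnot(is.character(series_id), length(series_id) == 1L,
            length(first_year) == 1L, is.numeric(widths))
  if (length(widths) == 0L)
    stop("ring_series: 'widths' must be non-empty", call. = FALSE)
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("ring_series: all widths must be finite and > 0", call. = FALSE)
  if (pith_offset < 0 || pith_offset != round(pith_offset))
    stop("ring_series: 'pith_offset' must be a non-negative integer",
         call. = FALSE)
  structure(list(
    series_id   = series_id,
    tree_id     = tree_id,
    first_year  = as.integer(first_year),
    widths      = as.numeric(widths),
    pith_offset = as.integer(pith_offset),
    method      = method,
    last_year   = as.integer(first_year) + length(widths) - 1L
  ), class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series %s> tree %s, %d rings %d-%d (%s), pith offset %d\n",
              x$series_id, x$tree_id, length(x$widths),
              x$first_year, x$last_year, x$method, x$pith_offset))
  invisible(x)
}

#' @export
length.ring_series <- function(x) length(x$widths)

#' Years covered by a ring series
#' @param x A `ring_series`.
#' @return Integer vector `first_year:last_year`.
#' @export
series_years <- function(x) {
  stopifnot(inherits(x, "ring_series"))
  x$first_year:x$last_year
}

# Names of the environmental variables a climate table may carry.
CLIMATE_VARIABLES <- c("precipitation_mm", "nino12", "nino3", "nino34",
                       "nino4", "soi", "pdo", "gauge_level_cm")

#' Construct a monthly climate table
#'
#' Long-form monthly environmental series keyed by (year, month, variable).
#' Enforces one value per key and contiguous year coverage per variable.
#'
#' @param df Data frame with columns `year`, `month` (1--12), `variable`,
#'   `value`. Recognised variables: `r paste(CLIMATE_VARIABLES, collapse = ", ")`.
#' @return The validated data frame with class `c("climate_table", "data.frame")`.
#' @export
climate_table <- function(df) {
  need <- c("year", "month", "variable", "value")
  if (!all(need %in% names(df)))
    stop("climate_table: columns must include ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- df[need]
  df$year <- as.integer(df$year); df$month <- as.integer(df$month)
  df$variable <- as.character(df$variable); df$value <- as.numeric(df$value)
  if (any(df$month < 1L | df$month > 12L))
    stop("climate_table: month outside 1..12", call. = FALSE)
  bad <- setdiff(unique(df$variable), CLIMATE_VARIABLES)
  if (length(bad))
    stop("climate_table: unknown variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(df$year, df$month, df$variable)
  if (anyDuplicated(key))
    stop("climate_table: duplicate (year, month, variable) key: ",
         key[duplicated(key)][1L], call. = FALSE)
  # contiguous year coverage per variable; interior missing months are a
  # recorded warning, not an error (parsers surface them in the report)
  for (v in unique(df$variable)) {
    yr <- sort(unique(df$year[df$variable == v]))
    if (length(yr) > 1L && any(diff(yr) != 1L))
      stop("climate_table: non-contiguous year coverage for ", v, call. = FALSE)
  }
  df <- df[order(df$variable, df$year, df$month), ]
  rownames(df) <- NULL
  class(df) <- c("climate_table", "data.frame")
  df
}

#' Extract one variable from a climate table as a year x month matrix
#'
#' @param climate A `climate_table`.
#' @param variable Variable name.
#' @return Numeric matrix, rows named by year, 12 columns (months); `NA`
#'   where a month is missing.
#' @export
climate_matrix <- function(climate, variable) {
  stopifnot(inherits(climate, "climate_table"))
  d <- climate[climate$variable == variable, ]
  if (nrow(d) == 0L)
    stop("climate_matrix: variable not present: ", variable, call. = FALSE)
  yrs <- min(d$year):max(d$year)
  m <- matrix(NA_real_, length(yrs), 12L,
              dimnames = list(yrs, month.abb))
  m[cbind(match(d$year, yrs), d$month)] <- d$value
  m
}

#' Construct a daily river-gauge series
#'
#' @param df Data frame with columns `date` (Date or parseable) and
#'   `level_cm` (water level relative to gauge zero). Dates must be
#'   strictly increasing; missing days are allowed and flagged.
#' @return Data frame with class `c("gauge_series", "data.frame")` and an
#'   attribute `n_gaps` (count of missing calendar days inside the span).
#' @export
gauge_series <- function(df) {
  if (!all(c("date", "level_cm") %in% names(df)))
    stop("gauge_series: columns must include date, level_cm", call. = FALSE)
  df <- df[c("date", "level_cm")]
  df$date <- as.Date(df$date)
  df$level_cm <- as.numeric(df$level_cm)
  if (anyNA(df$date)) stop("gauge_series: unparseable date", call. = FALSE)
  if (is.unsorted(df$date, strictly = TRUE))
    stop("gauge_series: dates must be strictly increasing", call. = FALSE)
  span <- as.integer(max(df$date) - min(df$date)) + 1L
  attr(df, "n_gaps") <- span - nrow(df)
  class(df) <- c("gauge_series", "data.frame")
  df
}

#' Construct a tree inventory record table
#'
#' One row per tree: `tree_id`, `plot_id`, optional `cbh_cm`, `dbh_cm`,
#' optional `height_m`. If `dbh_cm` is missing but `cbh_cm` present it is
#' filled as `cbh_cm / pi`; if both are present they must agree to
#' rounding (0.05 cm).
#'
#' @param df Data frame of tree records.
#' @return Data frame with class `c("tree_records", "data.frame")`.
#' @export
tree_records <- function(df) {
  need <- c("tree_id", "plot_id")
  if (!all(need %in% names(df)))
    stop("tree_records: columns must include tree_id, plot_id", call. = FALSE)
  if (!"cbh_cm" %in% names(df)) df$cbh_cm <- NA_real_
  if (!"dbh_cm" %in% names(df)) df$dbh_cm <- NA_real_
  if (!"height_m" %in% names(df)) df$height_m <- NA_real_
  df$cbh_cm <- as.numeric(df$cbh_cm); df$dbh_cm <- as.numeric(df$dbh_cm)
  df$height_m <- as.numeric(df$height_m)
  fill <- is.na(df$dbh_cm) & !is.na(df$cbh_cm)
  df$dbh_cm[fill] <- df$cbh_cm[fill] / pi
  if (anyNA(df$dbh_cm))
    stop("tree_records: dbh_cm (or cbh_cm) required for every tree",
         call. = FALSE)
  if (any(df$dbh_cm <= 0))
    stop("tree_records: dbh_cm must be > 0", call. = FALSE)
  both <- !is.na(df$cbh_cm) & !fill
  if (any(both) && any(abs(df$dbh_cm[both] - df$cbh_cm[both] / pi) > 0.05))
    stop("tree_records: dbh_cm inconsistent with cbh_cm/pi", call. = FALSE)
  df <- df[c("tree_id", "plot_id", "cbh_cm", "dbh_cm", "height_m",
             setdiff(names(df), c("tree_id", "plot_id", "cbh_cm", "dbh_cm",
                                  "height_m")))]
  class(df) <- c("tree_records", "data.frame")
  df
}

#' Construct a plot record table
#'
#' One row per plot: `plot_id`, `area_m2` (default 250, a 50 x 5 m plot),
#' `water_mark_cm` (mean height of the flood mark above ground). Derived
#' columns `elevation_cm_gauge_datum` and `flood_days_per_year` are added
#' by [plot_elevation()] and [flood_days()].
#'
#' @param df Data frame of plot records.
#' @return Data frame with class `c("plot_records", "data.frame")`.
#' @export
plot_records <- function(df) {
  if (!"plot_id" %in% names(df))
    stop("plot_records: column plot_id required", call. = FALSE)
  if (!"area_m2" %in% names(df)) df$area_m2 <- 250
  if (!"water_mark_cm" %in% names(df)) df$water_mark_cm <- NA_real_
  df$area_m2 <- as.numeric(df$area_m2)
  df$water_mark_cm <- as.numeric(df$water_mark_cm)
  if (any(df$area_m2 <= 0)) stop("plot_records: area_m2 must be > 0",
                                 call. = FALSE)
  if (any(!is.na(df$water_mark_cm) & df$water_mark_cm < 0))
    stop("plot_records: water_mark_cm must be >= 0", call. = FALSE)
  if (anyDuplicated(df$plot_id))
    stop("plot_records: duplicate plot_id", call. = FALSE)
  class(df) <- c("plot_records", "data.frame")
  df
}
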