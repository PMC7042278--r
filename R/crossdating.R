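#' Gleichlaeufigkeit (percentage of parallel run)
#'
#' Year-to-year sign agreement of two aligned ring-width series over
#' their overlap: each of the n-1 consecutive intervals scores 1 when
#' both series move in the same direction (both up, both down, or both
#' unchanged), 0 when they move in opposite directions, and 1/2 when
#' exactly one is unchanged (the classical Eckstein--Bauch tie
#' convention). GLK is 100 times the mean score.
#'
#' @param x,y Numeric vectors, the aligned overlapping segments (same
#'   length).
#' @param min_overlap Minimum overlap length in years (default 2).
#' @return GLK in percent, in `[0, 100]`.
#' @examples
#' glk(c(1, 2, 3, 4), c(2, 3, 4, 5))  # 100
#' glk(c(1, 2, 1, 2), c(2, 1, 2, 1))  # 0
#' @export
glk <- function(x, y, min_overlap = 2L) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("glk: segments must be aligned to equal length", call. = FALSE)
  if (length(x) < max(2L, min_overlap))
    stop("glk: insufficient overlap (", length(x), " < ",
         max(2L, min_overlap), ")", call. = FALSE)
  dx <- sign(diff(x)); dy <- sign(diff(y))
  score <- ifelse(dx == dy, 1, ifelse(dx == 0 | dy == 0, 0.5, 0))
  100 * mean(score)
}

# Baillie-Pilcher pre-transform: index each series by its centered
# 5-year moving average, then take natural logs. Keeps the t statistic
# comparable across growth levels and removes the age trend.
bp_transform <- function(w) {
  log(index_series(w))
}

#' Baillie--Pilcher t value
#'
#' Student-t transform of the Pearson correlation between two ring-width
#' segments after the Baillie--Pilcher pre-transform (5-year
#' moving-average indexing followed by natural log):
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Perfect correlation is guarded by
#' capping at `t_cap`.
#'
#' @param x,y Aligned overlapping width segments (equal length, n >= 4;
#'   the moving-average transform additionally requires n >= 5).
#' @param transform Apply the Baillie--Pilcher pre-transform (default
#'   `TRUE`); set `FALSE` if the inputs are already transformed.
#' @param t_cap Cap returned when `r` is numerically 1 (default 100).
#' @return The t value (sign of `r` preserved).
#' @export
t_value_bp <- function(x, y, transform = TRUE, t_cap = 100) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("t_value_bp: segments must be aligned to equal length", call. = FALSE)
  if (length(x) < 4L)
    stop("t_value_bp: overlap must be >= 4 years", call. = FALSE)
  if (transform) {
    x <- bp_transform(x); y <- bp_transform(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("t_value_bp: zero variance in a transformed segment", call. = FALSE)
  r <- stats::cor(x, y)
  n <- length(x)
  if (1 - r^2 < 1e-12) return(sign(r) * t_cap)
  t <- r * sqrt((n - 2) / (1 - r^2))
  max(min(t, t_cap), -t_cap)
}

# Overlap of two dated series at a given shift of y (y moved later by
# `lag` years). Returns NULL when overlap < min_overlap.
overlap_segments <- function(x, y, lag, min_overlap) {
  ys_first <- y$first_year + lag
  lo <- max(x$first_year, ys_first)
  hi <- min(x$last_year, ys_first + length(y$widths) - 1L)
  n <- hi - lo + 1L
  if (n < min_overlap) return(NULL)
  list(x = x$widths[(lo - x$first_year + 1L):(hi - x$first_year + 1L)],
       y = y$widths[(lo - ys_first + 1L):(hi - ys_first + 1L)],
       n = n)
}

#' Find the best cross-dating lag between two dated series
#'
#' Slides `y` over `x` within `[-max_shift, +max_shift]` and keeps the
#' shift maximising GLK, breaking ties by t value and then
#' deterministically toward the smaller `|lag|` (and the positive lag on
#' an exact tie). A positive lag means `y` must be dated `lag` years
#' later than its nominal years to match `x`.
#'
#' @param x,y [ring_series()] objects.
#' @param max_shift Maximum shift searched, in years (>= 0).
#' @param min_overlap Minimum admissible overlap (default 10 years).
#' @param glk_min,t_min Admission thresholds applied to the best lag
#'   (defaults 60 and 2.0).
#' @return List with `lag` and a one-row data frame `report`
#'   (`id_x, id_y, lag, n, glk, t, admitted`).
#' @export
best_lag <- function(x, y, max_shift, min_overlap = 10L,
                     glk_min = 60, t_min = 2.0) {
  stopifnot(inherits(x, "ring_series"), inherits(y, "ring_series"),
            max_shift >= 0)
  lags <- seq.int(-max_shift, max_shift)
  # order so that on exact score ties the first (kept) candidate is the
  # smallest |lag|, positive before negative
  lags <- lags[order(abs(lags), -sign(lags))]
  best <- NULL
  for (L in lags) {
    seg <- overlap_segments(x, y, L, max(min_overlap, 5L))
    if (is.null(seg)) next
    g <- glk(seg$x, seg$y)
    tv <- tryCatch(t_value_bp(seg$x, seg$y), error = function(e) NA_real_)
    if (is.null(best) || g > best$g + 1e-12 ||
        (abs(g - best$g) <= 1e-12 && !is.na(tv) && !is.na(best$t) &&
         tv > best$t + 1e-12)) {
      best <- list(lag = L, g = g, t = tv, n = seg$n)
    }
  }
  if (is.null(best))
    stop("best_lag: no shift achieves the minimum overlap", call. = FALSE)
  report <- data.frame(
    id_x = x$series_id, id_y = y$series_id, lag = best$lag, n = best$n,
    glk = best$g, t = best$t,
    admitted = !is.na(best$t) && best$g >= glk_min && best$t >= t_min,
    stringsAsFactors = FALSE)
  list(lag = best$lag, report = report)
}

#' Estimate missing inner rings from the pith distance
#'
#' For a core that missed the pith, the number of unmeasured inner rings
#' is estimated as the measured distance to the pith divided by the mean
#' width of the `k` innermost measured rings, rounded to the nearest
#' integer.
#'
#' @param series A [ring_series()].
#' @param pith_distance_mm Distance from the innermost measured ring to
#'   the estimated pith position, in mm (>= 0).
#' @param k Number of innermost rings whose mean width is used
#'   (default 5; capped at the series length).
#' @return Integer ring count (stored by callers as `pith_offset`).
#' @export
estimate_missing_rings <- function(series, pith_distance_mm, k = 5L) {
  stopifnot(inherits(series, "ring_series"))
  if (pith_distance_mm < 0)
    stop("estimate_missing_rings: negative pith distance", call. = FALSE)
  k <- min(as.integer(k), length(series$widths))
  inner_mean <- mean(series$widths[seq_len(k)])
  as.integer(round(pith_distance_mm / inner_mean))
}

# Score one series against the mean raw-width curve of the others
# (leave-one-out), at lag 0.
loo_score <- function(series, idx, min_overlap) {
  target <- series[[idx]]
  others <- series[-idx]
  yrs <- min(vapply(others, `[[`, 1L, "first_year")):
         max(vapply(others, `[[`, 1L, "last_year"))
  acc <- matrix(NA_real_, length(others), length(yrs))
  for (j in seq_along(others)) {
    s <- others[[j]]
    acc[j, match(series_years(s), yrs)] <- s$widths
  }
  mcurve <- colMeans(acc, na.rm = TRUE)
  span <- range(which(!is.nan(mcurve)))
  seg_curve <- mcurve[span[1L]:span[2L]]
  if (anyNA(seg_curve) || any(is.nan(seg_curve)))
    stop("crossdate_set: mean curve has an interior coverage gap",
         call. = FALSE)
  ref <- ring_series("__MEAN__", first_year = yrs[span[1L]],
                     widths = seg_curve)
  seg <- overlap_segments(ref, target, 0L, max(min_overlap, 5L))
  if (is.null(seg)) return(c(glk = NA_real_, t = NA_real_, n = 0))
  g <- glk(seg$x, seg$y)
  tv <- tryCatch(t_value_bp(seg$x, seg$y), error = function(e) NA_real_)
  c(glk = g, t = tv, n = seg$n)
}

#' Iteratively admit cross-dated series to a chronology
#'
#' Leave-one-out screening: each series is scored (GLK and
#' Baillie--Pilcher t at lag 0) against the mean raw-width curve of all
#' other currently retained series; the single worst series failing
#' either threshold is dropped and the procedure repeats until every
#' retained series passes. Deterministic: ties broken by lowest t, then
#' input order.
#'
#' @param series List of dated [ring_series()] (>= 2).
#' @param glk_min,t_min Admission thresholds (defaults 60 and 2.0; the
#'   classical working values — site studies rarely publish their
#'   cut-offs, so these are explicit configuration, not inference).
#' @param min_overlap Minimum overlap with the mean curve (default 10).
#' @return List with `admitted` (retained series), `rejected` (ids) and
#'   `report` (data frame of per-series scores from the final round plus
#'   the round each rejection happened in).
#' @export
crossdate_set <- function(series, glk_min = 60, t_min = 2.0,
                          min_overlap = 10L) {
  stopifnot(is.list(series), length(series) >= 2L)
  ids <- vapply(series, `[[`, "", "series_id")
  names(series) <- ids
  keep <- rep(TRUE, length(series))
  rejected <- character(); round <- 0L
  repeat {
    round <- round + 1L
    live <- which(keep)
    if (length(live) < 2L)
      stop("crossdate_set: fewer than 2 series admitted", call. = FALSE)
    sc <- t(vapply(seq_along(live), function(i)
      loo_score(series[live], i, min_overlap), c(glk = 0, t = 0, n = 0)))
    fail <- is.na(sc[, "t"]) | sc[, "glk"] < glk_min | sc[, "t"] < t_min
    if (!any(fail)) {
      report <- data.frame(series_id = ids[live], glk = sc[, "glk"],
                           t = sc[, "t"], n = sc[, "n"], admitted = TRUE,
                           stringsAsFactors = FALSE)
      if (length(rejected))
        report <- rbind(report, data.frame(
          series_id = rejected, glk = NA_real_, t = NA_real_, n = NA_real_,
          admitted = FALSE, stringsAsFactors = FALSE))
      rownames(report) <- NULL
      return(list(admitted = series[live], rejected = rejected,
                  report = report))
    }
    tt <- sc[, "t"]; tt[is.na(tt)] <- -Inf
    worst <- live[which.min(replace(tt, !fail, Inf))]
    rejected <- c(rejected, ids[worst])
    keep[worst] <- FALSE
  }
}
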