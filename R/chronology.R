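#' Convert raw ring widths to growth indices
#'
#' Standardisation by a centred 5-year moving average: each width is
#' divided by the mean of the window centred on it, which removes the
#' age/size trend while keeping year-to-year variation. At the series
#' edges the window is clipped to the available years (3-term means at
#' the first and last year, 4-term at the second and second-to-last);
#' alternatively the two edge years on each side can be truncated.
#'
#' @param widths Numeric vector of positive ring widths (length >= 5).
#' @param edges `"shrink"` (default) keeps the full span using shrinking
#'   centred windows; `"truncate"` returns `NA` for the first and last
#'   two years.
#' @return Numeric vector of dimensionless indices, same length as
#'   `widths`, centred near 1.
#' @examples
#' index_series(c(2, 2, 2, 2, 2))  # all 1
#' @export
index_series <- function(widths, edges = c("shrink", "truncate")) {
  edges <- match.arg(edges)
  stopifnot(is.numeric(widths))
  n <- length(widths)
  if (n < 5L)
    stop("index_series: need at least 5 years", call. = FALSE)
  if (any(widths <= 0)) stop("index_series: widths must be > 0", call. = FALSE)
  cs <- cumsum(c(0, widths))
  i <- seq_len(n)
  lo <- pmax(i - 2L, 1L); hi <- pmin(i + 2L, n)
  ma <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  idx <- widths / ma
  if (edges == "truncate") idx[c(1L, 2L, n - 1L, n)] <- NA_real_
  idx
}

#' Build a mean chronology from aligned index series
#'
#' Per-year unweighted arithmetic mean of all available growth indices,
#' with the number of contributing series (sample depth) recorded for
#' every year. The span is the union of the input spans. Tukey's
#' biweight robust mean is available as an option for heavy-tailed index
#' distributions.
#'
#' @param indexed List of per-series index data: each element a list (or
#'   [ring_series()]-like) with `first_year` and `index` (numeric vector;
#'   `NA` allowed where a series has no index).
#' @param robust Use a biweight robust mean instead of the arithmetic
#'   mean (default `FALSE`).
#' @return Object of class `"chronology"`: data frame with columns
#'   `year`, `index`, `depth`, plus attribute `mean_sensitivity` (of the
#'   chronology index itself) and `n_series`.
#' @export
build_chronology <- function(indexed, robust = FALSE) {
  stopifnot(is.list(indexed), length(indexed) >= 1L)
  if (length(indexed) == 0L)
    stop("build_chronology: empty input", call. = FALSE)
  fy <- vapply(indexed, `[[`, 1, "first_year")
  iv <- lapply(indexed, `[[`, "index")
  yrs <- min(fy):max(fy + vapply(iv, length, 1L) - 1L)
  m <- matrix(NA_real_, length(indexed), length(yrs))
  for (j in seq_along(indexed))
    m[j, match(fy[j] + seq_along(iv[[j]]) - 1L, yrs)] <- iv[[j]]
  depth <- colSums(!is.na(m))
  mean_fun <- if (robust) biweight_mean else function(v) mean(v, na.rm = TRUE)
  index <- apply(m, 2L, function(v) if (all(is.na(v))) NA_real_ else mean_fun(v))
  out <- data.frame(year = yrs, index = index, depth = depth)
  out <- out[out$depth >= 1L, ]
  rownames(out) <- NULL
  ok <- !is.na(out$index)
  attr(out, "mean_sensitivity") <-
    if (sum(ok) >= 2L) mean_sensitivity(out$index[ok]) else NA_real_
  attr(out, "n_series") <- length(indexed)
  class(out) <- c("chronology", "data.frame")
  out
}

# Tukey biweight robust mean (c = 9, MAD scale), the robust location
# estimator conventional in chronology building.
biweight_mean <- function(v, c = 9) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  m <- stats::median(v)
  s <- stats::mad(v, center = m)
  if (s == 0) return(m)
  for (i in 1:10) {
    u <- (v - m) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * v) / sum(w)
    if (abs(m_new - m) < 1e-10) break
    m <- m_new
  }
  m
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology> %d-%d, %d series, mean sensitivity %.3f\n",
              min(x$year), max(x$year), attr(x, "n_series"),
              attr(x, "mean_sensitivity")))
  invisible(x)
}

#' Mean sensitivity of a ring-width (or index) series
#'
#' The mean absolute relative difference between consecutive values,
#' `MS = mean(|2 (x_i - x_{i-1}) / (x_i + x_{i-1})|)`, the classical
#' measure of year-to-year variability. MS lies in `[0, 2)` for positive
#' series and is scale invariant; values above 0.40 are conventionally
#' called high sensitivity to the environment.
#'
#' @param x Positive numeric vector, length >= 2.
#' @return Mean sensitivity.
#' @examples
#' mean_sensitivity(c(1, 3))     # 1
#' mean_sensitivity(c(1, 2, 1))  # 2/3
#' @export
mean_sensitivity <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) < 2L)
    stop("mean_sensitivity: need at least 2 values", call. = FALSE)
  s <- x[-1] + x[-length(x)]
  if (any(s == 0))
    stop("mean_sensitivity: adjacent pair sums to zero", call. = FALSE)
  mean(abs(2 * diff(x) / s))
}

#' Is a mean sensitivity "high"?
#'
#' Convention: MS above 0.40 indicates high environmental sensitivity.
#' @param ms Mean sensitivity value.
#' @param threshold Default 0.40.
#' @return Logical.
#' @export
is_high_sensitivity <- function(ms, threshold = 0.40) ms > threshold

#' Mean diameter increment of a series
#'
#' Twice the mean radial ring width: the average annual increment in
#' stem diameter, in mm/year.
#'
#' @param series A [ring_series()] or a numeric width vector (mm).
#' @return MDI in mm/year.
#' @export
mdi <- function(series) {
  w <- if (inherits(series, "ring_series")) series$widths else series
  stopifnot(is.numeric(w), length(w) >= 1L)
  2 * mean(w)
}
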