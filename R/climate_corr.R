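#' Build a lagged month window
#'
#' A month window is a data frame of (month, year_offset) pairs ordered
#' from earliest to latest, with offsets relative to the ring year:
#' -1 is the previous calendar year, 0 the ring year, +1 the next.
#' The default window runs from October of the previous year through
#' September of the following year (24 months), bracketing the southern
#' hemisphere growing season that starts in October.
#'
#' @param from_month,from_offset Start of the window (default Oct, -1).
#' @param to_month,to_offset End of the window (default Sep, +1).
#' @return Data frame with columns `month`, `year_offset`, `label`
#'   (e.g. `"Dec(-1)"`, `"Jan"`, `"Feb(+1)"`).
#' @export
month_window <- function(from_month = 10L, from_offset = -1L,
                         to_month = 9L, to_offset = 1L) {
  stopifnot(from_offset %in% -1:1, to_offset %in% -1:1)
  a <- from_offset * 12L + from_month
  b <- to_offset * 12L + to_month
  if (b < a) stop("month_window: window end precedes its start", call. = FALSE)
  lin <- a:b
  off <- ifelse(lin < 1L, -1L, ifelse(lin > 12L, 1L, 0L))
  mon <- lin - off * 12L
  lab <- paste0(month.abb[mon],
                ifelse(off == -1L, "(-1)", ifelse(off == 1L, "(+1)", "")))
  data.frame(month = mon, year_offset = off, label = lab,
             stringsAsFactors = FALSE)
}

#' Two-sided critical Pearson correlation
#'
#' The smallest `|r|` significant at level `alpha` with `n` pairs:
#' `r_crit = t_crit / sqrt(n - 2 + t_crit^2)` where `t_crit` is the
#' upper `1 - alpha/2` Student-t quantile at `n - 2` degrees of freedom.
#'
#' @param n Number of pairs (>= 3).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Critical correlation (e.g. ~0.339 at n = 34, alpha = 0.05).
#' @export
critical_r <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Correlate a chronology with monthly climate over a lagged window
#'
#' For each requested variable and each month in the window, computes
#' the Pearson correlation between the chronology index for ring year t
#' and the variable's value in that month of year t + offset, over all
#' years where both exist. Significance is the two-sided per-cell test
#' at `alpha` against [critical_r()] — no multiple-testing correction is
#' applied (the classical dashed-line convention of correlation-function
#' plots; a knowingly liberal choice, so treat isolated hits with care).
#'
#' @param chron A [build_chronology()] result (or data frame with
#'   `year`, `index`).
#' @param climate A [climate_table()].
#' @param variables Character vector of variable names to screen.
#' @param window Month window from [month_window()].
#' @param alpha Per-cell significance level (default 0.05).
#' @param min_overlap Minimum chronology-climate overlap in years
#'   (default 10).
#' @return Data frame of class `"climate_correlations"`: `variable`,
#'   `month`, `year_offset`, `label`, `r`, `n`, `r_crit`, `significant`.
#' @export
monthly_correlations <- function(chron, climate, variables,
                                 window = month_window(), alpha = 0.05,
                                 min_overlap = 10L) {
  stopifnot(is.data.frame(chron), all(c("year", "index") %in% names(chron)))
  missing_v <- setdiff(variables, unique(climate$variable))
  if (length(missing_v))
    stop("monthly_correlations: unknown variable(s): ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  out <- vector("list", length(variables))
  for (vi in seq_along(variables)) {
    v <- variables[[vi]]
    cm <- climate_matrix(climate, v)
    cyrs <- as.integer(rownames(cm))
    res <- window
    res$variable <- v
    res$r <- NA_real_; res$n <- NA_integer_
    for (k in seq_len(nrow(window))) {
      target <- chron$year + window$year_offset[k]
      row <- match(target, cyrs)
      val <- ifelse(is.na(row), NA_real_, cm[cbind(row, window$month[k])])
      ok <- !is.na(val) & !is.na(chron$index)
      n <- sum(ok)
      if (n < min_overlap)
        stop("monthly_correlations: overlap ", n, " < ", min_overlap,
             " years for ", v, " ", window$label[k], call. = FALSE)
      res$r[k] <- stats::cor(chron$index[ok], val[ok])
      res$n[k] <- n
    }
    out[[vi]] <- res
  }
  res <- do.call(rbind, out)
  res$r_crit <- critical_r(res$n, alpha)
  res$significant <- abs(res$r) > res$r_crit
  res <- res[c("variable", "month", "year_offset", "label", "r", "n",
               "r_crit", "significant")]
  rownames(res) <- NULL
  class(res) <- c("climate_correlations", "data.frame")
  res
}

#' Plot a monthly correlation function
#'
#' Bar chart of r by lagged month for one variable, with dashed lines at
#' the two-sided critical correlation.
#'
#' @param x A `"climate_correlations"` data frame.
#' @param variable Which variable to plot (default: the first present).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.climate_correlations <- function(x, variable = x$variable[1L], ...) {
  d <- x[x$variable == variable, ]
  bp <- graphics::barplot(d$r, names.arg = d$label, las = 2,
                          ylab = "Pearson r", main = variable,
                          ylim = range(c(d$r, d$r_crit, -d$r_crit)) * 1.15,
                          ...)
  graphics::abline(h = c(-1, 1) * d$r_crit[1L], lty = 2)
  graphics::abline(h = 0)
  invisible(bp)
}

#' Aggregate climate months into one value per growth year
#'
#' Sums or averages the values of the named (month, offset) cells for
#' each ring year: e.g. the October(-1)--April wet-season precipitation
#' total for ring year t.
#'
#' @param climate A [climate_table()].
#' @param variable Variable name.
#' @param months Data frame with `month` and `year_offset` columns (a
#'   [month_window()] or subset).
#' @param stat `"sum"` or `"mean"`.
#' @return Data frame `year`, `value` (years with any missing month
#'   dropped).
#' @export
seasonal_aggregate <- function(climate, variable, months,
                               stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  if (NROW(months) == 0L)
    stop("seasonal_aggregate: empty month set", call. = FALSE)
  cm <- climate_matrix(climate, variable)
  cyrs <- as.integer(rownames(cm))
  years <- cyrs  # candidate ring years
  vals <- matrix(NA_real_, length(years), nrow(months))
  for (k in seq_len(nrow(months))) {
    row <- match(years + months$year_offset[k], cyrs)
    vals[, k] <- ifelse(is.na(row), NA_real_, cm[cbind(row, months$month[k])])
  }
  agg <- if (stat == "sum") rowSums(vals) else rowMeans(vals)
  keep <- !is.na(agg)
  data.frame(year = years[keep], value = agg[keep])
}
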