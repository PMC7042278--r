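#' Convert circumference at breast height to diameter
#'
#' `DBH = CBH / pi`, applied after the inclusion rule: field protocols
#' include a tree only when its CBH reaches a threshold (default 15 cm;
#' for bifurcated stems the rule is applied to the largest stem).
#'
#' @param cbh_cm Circumference(s) at breast height, cm.
#' @param threshold_cm Inclusion threshold (default 15); `NULL` disables
#'   filtering.
#' @return Numeric vector of DBH values with attribute `"excluded"`
#'   giving the indices filtered out (their DBH is returned as `NA`).
#' @examples
#' cbh_to_dbh(15)  # 4.7746
#' @export
cbh_to_dbh <- function(cbh_cm, threshold_cm = 15) {
  stopifnot(is.numeric(cbh_cm))
  if (any(cbh_cm <= 0)) stop("cbh_to_dbh: CBH must be > 0", call. = FALSE)
  dbh <- cbh_cm / pi
  excluded <- integer()
  if (!is.null(threshold_cm)) {
    excluded <- which(cbh_cm < threshold_cm)
    dbh[excluded] <- NA_real_
  }
  attr(dbh, "excluded") <- excluded
  dbh
}

#' Sturges diameter classes
#'
#' Partitions DBH values into `K = round(1 + 3.3 log10 N)` classes
#' (Sturges' count, rounded half up) of constant width `A / K`, where
#' `A = max - min` is the data breadth. Classes are half-open
#' `[lo, hi)` except the last, which is closed at the maximum.
#' Optionally attaches per-class age spans obtained by inverting the
#' class DBH boundaries through a fitted growth model.
#'
#' @param dbh Numeric vector of DBH values (N >= 2, not all equal).
#' @param fit Optional `"growth_fit"` used to add age bounds per class
#'   (edges at or above the asymptote are clamped to the age of the
#'   largest invertible DBH present).
#' @param k Optional forced class count overriding Sturges.
#' @return Object of class `"diameter_classing"`: list with `N`, `A`,
#'   `K`, `width`, `edges` (length K+1), `counts`, `table` (per-class
#'   data frame with labels, counts and, when `fit` is given,
#'   `age_lo`/`age_hi`).
#' @examples
#' set.seed(1)
#' make_classes(runif(100, 5, 60))$K  # 8
#' @export
make_classes <- function(dbh, fit = NULL, k = NULL) {
  dbh <- dbh[!is.na(dbh)]
  n <- length(dbh)
  if (n < 2L) stop("make_classes: need N >= 2 values", call. = FALSE)
  a <- max(dbh) - min(dbh)
  if (a == 0) stop("make_classes: degenerate breadth (all values equal)",
                   call. = FALSE)
  k <- if (is.null(k)) floor(1 + 3.3 * log10(n) + 0.5) else as.integer(k)
  width <- a / k
  edges <- min(dbh) + width * 0:k
  edges[k + 1L] <- max(dbh)  # guard the closed top edge against rounding
  cls <- pmin(floor((dbh - edges[1L]) / width) + 1L, k)
  counts <- tabulate(cls, nbins = k)
  tab <- data.frame(
    class = seq_len(k),
    dbh_lo = edges[-(k + 1L)], dbh_hi = edges[-1L],
    label = sprintf("%.2f-%.2f", edges[-(k + 1L)], edges[-1L]),
    count = counts)
  if (!is.null(fit)) {
    p <- growth_params(fit)
    if (!any(dbh < p["b0"]))
      stop("make_classes: no DBH below the model asymptote", call. = FALSE)
    cap <- max(dbh[dbh < p["b0"]])  # largest invertible DBH present
    ages <- age_from_dbh(fit, pmin(edges, cap))
    tab$age_lo <- ages[-(k + 1L)]
    tab$age_hi <- ages[-1L]
  }
  structure(list(N = n, A = a, K = k, width = width, edges = edges,
                 counts = counts, table = tab),
            class = "diameter_classing")
}

#' @export
print.diameter_classing <- function(x, ...) {
  cat(sprintf("<diameter_classing> N = %d, breadth = %.2f cm, K = %d, width = %.2f cm\n",
              x$N, x$A, x$K, x$width))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Assign model ages to inventoried trees
#'
#' Applies [age_from_dbh()] to every record. Trees at or above the
#' model's asymptotic DBH have no finite model age; they are flagged
#' and assigned the age of the largest invertible DBH in the data.
#'
#' @param records A [tree_records()] data frame.
#' @param fit A `"growth_fit"`.
#' @return `records` with added columns `age_yr` and `age_flagged`.
#' @export
assign_ages <- function(records, fit) {
  p <- growth_params(fit)
  dbh <- records$dbh_cm
  flag <- dbh >= p["b0"]
  if (all(flag))
    stop("assign_ages: no DBH below the model asymptote", call. = FALSE)
  age <- rep(NA_real_, length(dbh))
  age[!flag] <- age_from_dbh(fit, dbh[!flag])
  if (any(flag)) age[flag] <- max(age, na.rm = TRUE)
  records$age_yr <- age
  records$age_flagged <- flag
  records
}

#' Chi-square comparison of diameter-class counts between flood categories
#'
#' Pearson chi-square (no continuity correction) on the
#' category x diameter-class contingency table. Classes whose expected
#' count falls below `min_expected` are pooled into their nearest
#' neighbouring class (from the sparse top end downwards) before
#' testing; pooling is reported.
#'
#' @param counts_by_category Matrix (or data frame) with one row per
#'   flood category and one column per diameter class, sharing class
#'   edges; or a list of two count vectors.
#' @param min_expected Pooling threshold on expected counts (default 1).
#' @return List: `statistic` (X-squared), `df`, `p_value`, `table` (the
#'   tested, possibly pooled, table), `pooled` (character log).
#' @export
flood_class_chisq <- function(counts_by_category, min_expected = 1) {
  m <- if (is.list(counts_by_category) && !is.data.frame(counts_by_category))
    do.call(rbind, counts_by_category) else as.matrix(counts_by_category)
  stopifnot(nrow(m) == 2L, ncol(m) >= 2L)
  pooled <- character()
  repeat {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    bad <- which(apply(e, 2L, min) < min_expected)
    if (!length(bad) || ncol(m) == 2L) break
    j <- bad[length(bad)]              # pool the highest sparse class
    nb <- if (j == 1L) 2L else j - 1L  # into its lower neighbour
    pooled <- c(pooled, sprintf("class %d pooled into class %d", j, nb))
    m[, nb] <- m[, nb] + m[, j]
    m <- m[, -j, drop = FALSE]
  }
  if (all(m == m[1L, 1L])) {
    # identical uniform table: chisq.test would warn; statistic is 0
    return(list(statistic = 0, df = (nrow(m) - 1) * (ncol(m) - 1),
                p_value = 1, table = m, pooled = pooled))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = m, pooled = pooled)
}

# Compact letter display from Tukey HSD pairwise p-values: groups that
# cannot be distinguished at `alpha` share a letter (insert-and-absorb).
tukey_letters <- function(pmat, levels, alpha = 0.05) {
  k <- length(levels)
  compatible <- function(i, members) all(vapply(members, function(j) {
    p <- pmat[max(i, j), min(i, j)]
    is.na(p) || p > alpha
  }, logical(1)))
  groups <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (compatible(i, groups[[g]])) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups <- c(groups, list(i))
  }
  # drop groups fully contained in another
  keep <- !vapply(seq_along(groups), function(g)
    any(vapply(seq_along(groups), function(h)
      h != g && all(groups[[g]] %in% groups[[h]]), logical(1))), logical(1))
  groups <- groups[keep]
  letters_out <- character(k)
  for (g in seq_along(groups))
    for (i in groups[[g]])
      letters_out[i] <- paste0(letters_out[i], letters[g])
  stats::setNames(letters_out, levels)
}

#' Environmental history across the young diameter/age classes
#'
#' For each of the leading diameter classes holding more than
#' `min_count` individuals (at most `max_classes`; larger classes are
#' excluded because their counts decay for demographic, not
#' environmental, reasons), takes the class's
#' establishment-year span — survey year minus the age bounds obtained by
#' inverting the class DBH boundaries — and collects, for every year in
#' the span, the annual maximum flood level, annual minimum flood level,
#' and total precipitation. Each variable is then compared across
#' classes by one-way ANOVA, followed by Tukey HSD at 5% (with compact
#' letter display) when the ANOVA is significant.
#'
#' @param classing A [make_classes()] result carrying age bounds (i.e.
#'   built with `fit`).
#' @param climate A [climate_table()] containing `precipitation_mm`.
#' @param gauge A [gauge_series()].
#' @param survey_year Calendar year of the inventory.
#' @param n_classes Number of leading classes compared; `NULL` (default)
#'   selects the longest leading run of classes with more than
#'   `min_count` individuals, capped at `max_classes`.
#' @param max_classes Cap on the automatic selection (default 5).
#' @param min_count Qualifying count, exclusive (default 5).
#' @param alpha Significance level for the ANOVA gate (default 0.05).
#' @return List with `spans` (per-class year ranges), `data` (long
#'   data frame year/class/variable/value), `anova` (per-variable F, df,
#'   p), `tukey` (per-variable Tukey table and letters, `NULL` where the
#'   ANOVA is not significant).
#' @export
climate_by_age_class <- function(classing, climate, gauge, survey_year,
                                 n_classes = NULL, max_classes = 5L,
                                 min_count = 5L, alpha = 0.05) {
  stopifnot(inherits(classing, "diameter_classing"))
  tab <- classing$table
  if (!"age_lo" %in% names(tab))
    stop("climate_by_age_class: classing lacks age bounds (pass `fit` to make_classes)",
         call. = FALSE)
  if (is.null(n_classes)) {
    qual <- tab$count > min_count
    lead <- which(!qual)[1L] - 1L
    n_classes <- min(if (is.na(lead)) nrow(tab) else lead, max_classes)
    if (n_classes < 2L)
      stop("climate_by_age_class: fewer than 2 leading classes with > ",
           min_count, " individuals", call. = FALSE)
  }
  if (nrow(tab) < n_classes)
    stop("climate_by_age_class: fewer than ", n_classes, " classes",
         call. = FALSE)
  use <- tab[seq_len(n_classes), ]
  if (any(use$count <= min_count))
    stop("climate_by_age_class: class(es) with <= ", min_count,
         " individuals among the first ", n_classes, call. = FALSE)

  spans <- lapply(seq_len(n_classes), function(i) {
    yr_hi <- floor(survey_year - use$age_lo[i])
    yr_lo <- ceiling(survey_year - use$age_hi[i])
    if (yr_lo > yr_hi)
      stop("climate_by_age_class: empty establishment span for class ", i,
           call. = FALSE)
    yr_lo:yr_hi
  })
  names(spans) <- paste0("class", seq_len(n_classes))

  # annual summaries from the gauge and precipitation records
  gyear <- as.integer(format(gauge$date, "%Y"))
  gmax <- tapply(gauge$level_cm, gyear, max)
  gmin <- tapply(gauge$level_cm, gyear, min)
  pr <- seasonal_aggregate(climate, "precipitation_mm",
                           data.frame(month = 1:12, year_offset = 0L), "sum")
  rows <- list()
  for (i in seq_len(n_classes)) {
    yrs <- spans[[i]]
    rows[[i]] <- data.frame(
      class = factor(rep(i, 3 * length(yrs)), levels = seq_len(n_classes)),
      year = rep(yrs, 3),
      variable = rep(c("flood_max_cm", "flood_min_cm", "precip_total_mm"),
                     each = length(yrs)),
      value = c(gmax[as.character(yrs)], gmin[as.character(yrs)],
                pr$value[match(yrs, pr$year)]))
  }
  long <- do.call(rbind, rows)
  if (anyNA(long$value))
    stop("climate_by_age_class: establishment span not covered by the ",
         "gauge/climate records", call. = FALSE)

  anova_out <- list(); tukey_out <- list()
  for (v in unique(long$variable)) {
    d <- long[long$variable == v, ]
    fit <- stats::aov(value ~ class, data = d)
    an <- summary(fit)[[1]]
    anova_out[[v]] <- data.frame(
      variable = v, F = an[1, "F value"],
      df1 = an[1, "Df"], df2 = an[2, "Df"], p = an[1, "Pr(>F)"])
    if (an[1, "Pr(>F)"] < alpha) {
      th <- stats::TukeyHSD(fit, conf.level = 0.95)$class
      lv <- levels(d$class)
      pmat <- matrix(NA_real_, length(lv), length(lv))
      pair <- do.call(rbind, strsplit(rownames(th), "-"))
      pmat[cbind(match(pair[, 1], lv), match(pair[, 2], lv))] <- th[, "p adj"]
      tukey_out[[v]] <- list(
        table = th,
        letters = tukey_letters(pmat, paste0("class", lv), alpha = alpha))
    } else tukey_out[v] <- list(NULL)
  }
  list(spans = spans, data = long,
       anova = do.call(rbind, c(anova_out, make.row.names = FALSE)),
       tukey = tukey_out)
}
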