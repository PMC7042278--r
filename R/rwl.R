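#' Read a Tucson/RWL ring-width archive
#'
#' Parses the standard decadal ("Tucson") ring-width exchange format:
#' each line carries an 8-character series ID, the year of the first
#' value on the line, and up to ten integer widths; a series ends with a
#' sentinel value, `999` for the 0.01 mm dialect or `-9999` for the
#' 0.001 mm dialect. Widths are converted to mm using the dialect implied
#' by the sentinel. Both dialects are accepted on read.
#'
#' @param path Path to an RWL file.
#' @return A named list of [ring_series()] objects. The parse report
#'   (series count, line count, dialect per series) is attached as
#'   attribute `"parse_report"`.
#' @seealso [write_rwl()]
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop("read_rwl: no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]

  out <- list()
  dialects <- character()
  cur_id <- NULL; cur_first <- NULL; cur_vals <- integer(); cur_next <- NULL

  flush_series <- function() {
    if (is.null(cur_id)) return(invisible())
    stop("read_rwl: series '", cur_id, "' not terminated by a sentinel",
         call. = FALSE)
  }

  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    id <- trimws(substr(ln, 1L, 8L))
    rest <- trimws(substr(ln, 9L, nchar(ln)))
    toks <- strsplit(rest, "[ \t]+")[[1]]
    if (length(toks) < 2L || !nzchar(id))
      stop("read_rwl: malformed line ", lineno[k], call. = FALSE)
    nums <- suppressWarnings(as.integer(toks))
    if (anyNA(nums))
      stop("read_rwl: malformed line ", lineno[k],
           " (non-numeric field)", call. = FALSE)
    year <- nums[1L]; vals <- nums[-1L]

    if (is.null(cur_id) || id != cur_id) {
      flush_series()
      cur_id <- id; cur_first <- year; cur_vals <- integer(); cur_next <- year
    } else {
      if (year < cur_next)
        stop("read_rwl: non-monotone decade years at line ", lineno[k],
             call. = FALSE)
      if (year != cur_next)
        stop("read_rwl: non-contiguous decades at line ", lineno[k],
             " (expected year ", cur_next, ", found ", year, ")",
             call. = FALSE)
    }

    sent <- match(TRUE, vals == 999L | vals == -9999L)
    if (!is.na(sent)) {
      dialect <- if (vals[sent] == 999L) 0.01 else 0.001
      vals <- vals[seq_len(sent - 1L)]
      cur_vals <- c(cur_vals, vals)
      if (length(cur_vals) == 0L)
        stop("read_rwl: empty series '", cur_id, "' at line ", lineno[k],
             call. = FALSE)
      if (any(cur_vals <= 0L))
        stop("read_rwl: non-positive width in series '", cur_id, "'",
             call. = FALSE)
      out[[cur_id]] <- ring_series(cur_id, first_year = cur_first,
                                   widths = cur_vals * dialect)
      dialects[cur_id] <- if (dialect == 0.01) "0.01mm" else "0.001mm"
      cur_id <- NULL
    } else {
      cur_vals <- c(cur_vals, vals)
      cur_next <- year + length(vals)
      # after the first (partial) line, lines start on decade boundaries
      if (cur_next %% 10L != 0L && k < length(lines)) {
        nxt_id <- trimws(substr(lines[[k + 1L]], 1L, 8L))
        if (identical(nxt_id, cur_id))
          stop("read_rwl: line ", lineno[k],
               " does not fill its decade", call. = FALSE)
      }
    }
  }
  flush_series()

  attr(out, "parse_report") <- list(
    n_series = length(out), n_lines = length(lines),
    n_values = vapply(out, function(s) length(s$widths), integer(1)),
    dialect = dialects)
  out
}

#' Write a Tucson/RWL ring-width archive
#'
#' Emits the 0.01 mm dialect (integer hundredths of a mm, series
#' terminated by the sentinel `999`), the precision of measuring benches
#' used for tropical ring widths. Output is re-readable by [read_rwl()]
#' to identical content.
#'
#' @param series A list of [ring_series()] objects (an empty list writes
#'   an empty, valid file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path) {
  stopifnot(is.list(series))
  con <- file(path, "w"); on.exit(close(con))
  for (s in series) {
    stopifnot(inherits(s, "ring_series"))
    if (nchar(s$series_id) > 8L)
      stop("write_rwl: series_id longer than 8 characters: ", s$series_id,
           call. = FALSE)
    v <- as.integer(round(s$widths * 100))
    if (any(v > 9999L))
      stop("write_rwl: width exceeds the 4-digit field (> 99.99 mm) in '",
           s$series_id, "'", call. = FALSE)
    if (any(v <= 0L))
      stop("write_rwl: width rounds to a non-positive field in '",
           s$series_id, "'", call. = FALSE)
    years <- series_years(s)
    vals <- c(v, 999L)          # sentinel occupies the year slot after the last
    yr_of_val <- c(years, s$last_year + 1L)
    row <- yr_of_val %/% 10L
    for (dec in unique(row)) {
      i <- which(row == dec)
      cat(sprintf("%-8s%4d%s", s$series_id, yr_of_val[i[1L]],
                  paste0(sprintf("%6d", vals[i]), collapse = "")),
          "\n", sep = "", file = con)
    }
  }
  invisible(path)
}

#' Read a long-form monthly climate CSV
#'
#' Schema: columns `year, month, variable, value` (RFC-4180 CSV).
#' Duplicate (year, month, variable) keys are an error; months missing
#' inside a variable's covered span are recorded as gap warnings in the
#' attached parse report, not dropped silently.
#'
#' @param path CSV path.
#' @return A [climate_table()] with attribute `"parse_report"` listing
#'   row counts and any coverage gaps.
#' @export
read_climate_csv <- function(path) {
  if (!file.exists(path)) stop("read_climate_csv: no such file: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- climate_table(raw)
  gaps <- character()
  for (v in unique(tab$variable)) {
    d <- tab[tab$variable == v, ]
    span <- expand.grid(month = 1:12, year = min(d$year):max(d$year))
    have <- paste(d$year, d$month)
    miss <- with(span, paste(year, month))[!with(span, paste(year, month)) %in% have]
    if (length(miss))
      gaps <- c(gaps, paste0(v, ": missing ", length(miss), " month(s)"))
  }
  attr(tab, "parse_report") <- list(n_rows_in = nrow(raw),
                                    n_rows_out = nrow(tab), gaps = gaps)
  tab
}

#' Read a daily river-gauge CSV
#'
#' Schema: columns `date` (ISO-8601) and `level_cm` (water level in cm
#' above gauge zero; the datum unit is configurable in study configs but
#' cm is the package-wide default).
#'
#' @param path CSV path.
#' @return A [gauge_series()].
#' @export
read_gauge_csv <- function(path) {
  if (!file.exists(path)) stop("read_gauge_csv: no such file: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  gauge_series(raw)
}

#' Read a tree/plot inventory CSV pair
#'
#' `trees_path` needs columns `tree_id, plot_id` and at least one of
#' `cbh_cm` / `dbh_cm` (plus optional `height_m`); `plots_path` needs
#' `plot_id` with optional `area_m2`, `water_mark_cm`. Every tree must
#' reference a known plot.
#'
#' @param trees_path,plots_path CSV paths.
#' @return List with elements `trees` ([tree_records()]) and `plots`
#'   ([plot_records()]).
#' @export
read_inventory_csv <- function(trees_path, plots_path) {
  trees <- tree_records(utils::read.csv(trees_path, stringsAsFactors = FALSE))
  plots <- plot_records(utils::read.csv(plots_path, stringsAsFactors = FALSE))
  orphan <- setdiff(trees$plot_id, plots$plot_id)
  if (length(orphan))
    stop("read_inventory_csv: trees reference unknown plot(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  list(trees = trees, plots = plots)
}
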