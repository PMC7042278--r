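#' Cumulative diameter growth curve of one tree
#'
#' Converts a dated ring-width series into (cambial age, cumulative DBH)
#' pairs: cumulative diameter is twice the running sum of radial widths
#' (mm converted to cm), then proportionally rescaled so the final value
#' equals the DBH measured in the field — a multiplicative correction
#' absorbing bark thickness and off-centre core bias. Ages are offset by
#' the series' pith offset.
#'
#' @param series A [ring_series()].
#' @param field_dbh_cm Field-measured DBH in cm (> 0). `NULL` skips the
#'   rescaling (scale factor 1).
#' @return Data frame `age` (years), `dbh_cm`, with attribute
#'   `"scale_factor"`.
#' @examples
#' s <- ring_series("A", first_year = 2000, widths = c(5, 5, 5))
#' cumulative_curve(s, field_dbh_cm = 4.5)  # scale factor 1.5
#' @export
cumulative_curve <- function(series, field_dbh_cm = NULL) {
  stopifnot(inherits(series, "ring_series"))
  cum_dbh <- 2 * cumsum(series$widths) / 10  # radial mm -> diameter cm
  sf <- 1
  if (!is.null(field_dbh_cm)) {
    if (field_dbh_cm <= 0)
      stop("cumulative_curve: field DBH must be > 0", call. = FALSE)
    sf <- field_dbh_cm / cum_dbh[length(cum_dbh)]
    cum_dbh <- cum_dbh * sf
  }
  out <- data.frame(age = series$pith_offset + seq_along(cum_dbh),
                    dbh_cm = cum_dbh)
  attr(out, "scale_factor") <- sf
  out
}

#' Sigmoidal age--diameter model: DBH from age
#'
#' Evaluates `DBH = b0 / (1 + (b1 / age)^b2)`: `b0` is the asymptotic
#' DBH (cm), `b1` the age at half the asymptote (years), `b2` a
#' dimensionless shape exponent.
#'
#' @param fit A `"growth_fit"` object or a named vector/list with `b0`,
#'   `b1`, `b2`.
#' @param age Age(s) in years (> 0).
#' @return Predicted DBH in cm.
#' @examples
#' dbh_from_age(c(b0 = 60, b1 = 20, b2 = 2), age = 10)  # 12
#' @export
dbh_from_age <- function(fit, age) {
  p <- growth_params(fit)
  if (any(age <= 0)) stop("dbh_from_age: age must be > 0", call. = FALSE)
  unname(p["b0"] / (1 + (p["b1"] / age)^p["b2"]))
}

#' Sigmoidal age--diameter model: age from DBH
#'
#' Closed-form inversion `age = b1 / (b0/DBH - 1)^(1/b2)`, defined for
#' `0 < DBH < b0` (the model never reaches its asymptote at finite age).
#'
#' @inheritParams dbh_from_age
#' @param dbh DBH value(s) in cm, strictly between 0 and `b0`.
#' @return Age(s) in years.
#' @export
age_from_dbh <- function(fit, dbh) {
  p <- growth_params(fit)
  if (any(dbh <= 0) || any(dbh >= p["b0"]))
    stop("age_from_dbh: DBH must lie strictly between 0 and the asymptote b0 (",
         format(p["b0"]), " cm)", call. = FALSE)
  unname(p["b1"] / (p["b0"] / dbh - 1)^(1 / p["b2"]))
}

growth_params <- function(fit) {
  if (inherits(fit, "growth_fit")) return(fit$coefficients)
  p <- unlist(fit)
  if (!all(c("b0", "b1", "b2") %in% names(p)))
    stop("expected b0, b1, b2 parameters", call. = FALSE)
  if (any(p[c("b0", "b1", "b2")] <= 0))
    stop("growth parameters must be > 0", call. = FALSE)
  p[c("b0", "b1", "b2")]
}

#' Fit the sigmoidal age--diameter growth model
#'
#' Nonlinear least squares of `DBH = b0 / (1 + (b1/age)^b2)` on pooled
#' (age, DBH) points. By default the points are first collapsed to the
#' mean diameter at each age across trees (the mean diameter growth
#' curve) before fitting; pooled-point fitting is available with
#' `average = FALSE`, and both r-squared flavours are reported.
#' Initialisation: `b0` at 1.2 x the maximum observed DBH, `b1` at the
#' age whose (mean) DBH is nearest half of that, `b2` at 1.
#'
#' @param age,dbh Numeric vectors of ages (years) and diameters (cm),
#'   equal length; or `age` may be a data frame with columns `age`,
#'   `dbh_cm` (e.g. stacked [cumulative_curve()] outputs).
#' @param average Fit the per-age mean curve (default `TRUE`) rather
#'   than the raw pooled points.
#' @param control Passed to [minpack.lm::nlsLM()] (tolerances, maximum
#'   iterations).
#' @return Object of class `"growth_fit"` with elements `coefficients`
#'   (`b0`, `b1`, `b2`), `r2` (of the curve actually fitted), `r2_pooled`
#'   (against all input points), `sigma` (residual sd), `fitted`,
#'   `residuals`, `data`, and the underlying `nls` object. Standard
#'   methods (`print`, `summary`, `coef`, `predict`, `residuals`,
#'   `plot`, `simulate`) apply.
#' @export
fit_sigmoidal <- function(age, dbh = NULL, average = TRUE,
                          control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (is.data.frame(age)) {
    dbh <- age$dbh_cm; age <- age$age
  }
  stopifnot(is.numeric(age), is.numeric(dbh), length(age) == length(dbh))
  ok <- is.finite(age) & is.finite(dbh)
  age <- age[ok]; dbh <- dbh[ok]
  if (length(unique(age)) < 3L)
    stop("fit_sigmoidal: need >= 3 distinct ages", call. = FALSE)
  if (stats::sd(dbh) == 0)
    stop("fit_sigmoidal: degenerate input (all DBH identical)", call. = FALSE)
  pooled <- data.frame(age = age, dbh = dbh)
  d <- if (average)
    stats::aggregate(dbh ~ age, data = pooled, FUN = mean)
  else pooled
  b0_0 <- 1.2 * max(d$dbh)
  b1_0 <- d$age[which.min(abs(d$dbh - b0_0 / 2))]
  if (b1_0 <= 0) b1_0 <- stats::median(d$age)
  fit <- tryCatch(
    minpack.lm::nlsLM(dbh ~ b0 / (1 + (b1 / age)^b2), data = d,
                      start = list(b0 = b0_0, b1 = b1_0, b2 = 1),
                      lower = c(1e-8, 1e-8, 1e-8), control = control),
    error = function(e) stop("fit_sigmoidal: fit failure: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  names(cf) <- c("b0", "b1", "b2")
  r2 <- function(obs, pred) {
    ss <- sum((obs - mean(obs))^2)
    if (ss == 0) return(NA_real_)
    1 - sum((obs - pred)^2) / ss
  }
  pred_d <- stats::predict(fit)
  pred_pooled <- cf["b0"] / (1 + (cf["b1"] / pooled$age)^cf["b2"])
  structure(list(
    coefficients = cf,
    r2 = r2(d$dbh, pred_d),
    r2_pooled = r2(pooled$dbh, pred_pooled),
    sigma = stats::sigma(fit),
    fitted = pred_d,
    residuals = d$dbh - pred_d,
    data = d,
    data_pooled = pooled,
    averaged = average,
    nls = fit
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Sigmoidal age-diameter growth model\n")
  cat("  DBH = b0 / (1 + (b1/age)^b2)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  r2 (%s) = %.3f, r2 (pooled) = %.3f, residual sd = %.3f cm\n",
              if (x$averaged) "mean curve" else "pooled", x$r2, x$r2_pooled,
              x$sigma))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  s <- summary(object$nls)
  rownames(s$coefficients) <- c("b0 (asymptotic DBH, cm)",
                                "b1 (age at half asymptote, yr)",
                                "b2 (shape)")
  peak <- increment_curve(object)
  structure(list(coefficients = s$coefficients, r2 = object$r2,
                 r2_pooled = object$r2_pooled, sigma = object$sigma,
                 n = nrow(object$data), peak = peak),
            class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat("Sigmoidal age-diameter growth model: DBH = b0 / (1 + (b1/age)^b2)\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nr2 = %.3f (fitted curve), %.3f (pooled points); sd = %.3f cm; n = %d\n",
              x$r2, x$r2_pooled, x$sigma, x$n))
  cat(sprintf("Maximum annual increment %.2f cm/yr at age %.2f yr%s\n",
              x$peak$increment_cm_yr, x$peak$age,
              if (x$peak$boundary) " (boundary: increment is monotone)" else ""))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) object$data$age else
    if (is.data.frame(newdata)) newdata$age else newdata
  dbh_from_age(object, age)
}

#' @export
plot.growth_fit <- function(x, ...) {
  graphics::plot(x$data_pooled$age, x$data_pooled$dbh,
                 xlab = "Cambial age (yr)", ylab = "DBH (cm)",
                 col = "grey60", ...)
  ag <- seq(0.1, max(x$data_pooled$age) * 1.1, length.out = 200)
  graphics::lines(ag, dbh_from_age(x, ag), lwd = 2)
  invisible(x)
}

#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  out <- as.data.frame(replicate(
    nsim, stats::fitted(object$nls) + stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Age and size of the maximum annual diameter increment
#'
#' Maximises the analytic derivative of the sigmoidal model on a fine
#' age grid (default step 0.01 yr), with deterministic tie-break toward
#' the smallest age. For `b2 <= 1` the increment is monotone decreasing,
#' so the maximum sits at the grid's lower boundary and is flagged.
#'
#' @param fit A `"growth_fit"` (or `b0`, `b1`, `b2` vector).
#' @param age_max Upper end of the searched grid (default `4 * b1`).
#' @param step Grid step in years (default 0.01).
#' @return List: `age`, `increment_cm_yr`, `boundary` (logical).
#' @export
increment_curve <- function(fit, age_max = NULL, step = 0.01) {
  p <- growth_params(fit)
  if (is.null(age_max)) age_max <- 4 * p["b1"]
  grid <- seq(step, age_max, by = step)
  u <- (p["b1"] / grid)^p["b2"]
  deriv <- p["b0"] * p["b2"] * u / (grid * (1 + u)^2)
  i <- which.max(deriv)  # which.max returns the first (smallest age) tie
  list(age = unname(grid[i]), increment_cm_yr = unname(deriv[i]),
       boundary = i == 1L)
}

#' Fit a saturating diameter--height model
#'
#' Least-squares fit of the rectangular hyperbola `H = a * DBH / (b + DBH)`
#' (`a` = asymptotic height in m, `b` = DBH at half the asymptotic
#' height, cm) — a standard two-parameter saturating allometry for
#' tropical trees. The functional form is configurable via `formula`
#' should another saturating shape be preferred.
#'
#' @param records A [tree_records()] data frame (uses `dbh_cm`,
#'   `height_m`) or a data frame with those columns.
#' @param formula Optional alternative model formula in `height_m` and
#'   `dbh_cm` with parameters `a`, `b`.
#' @return Object of class `"height_fit"`: `coefficients` (`a`, `b`),
#'   `r2`, `sigma`, `nls`, `data`.
#' @export
fit_height_model <- function(records,
                             formula = height_m ~ a * dbh_cm / (b + dbh_cm)) {
  d <- records[stats::complete.cases(records[c("dbh_cm", "height_m")]), ]
  if (nrow(d) < 3L)
    stop("fit_height_model: need >= 3 records with height", call. = FALSE)
  if (length(unique(d$dbh_cm)) < 2L)
    stop("fit_height_model: fit failure: single DBH value", call. = FALSE)
  # linearized start: 1/H = 1/a + (b/a) (1/DBH)
  lin <- stats::coef(stats::lm(I(1 / height_m) ~ I(1 / dbh_cm), data = d))
  start <- list(a = unname(1 / lin[1L]), b = unname(lin[2L] / lin[1L]))
  if (!all(is.finite(unlist(start))) || any(unlist(start) <= 0))
    start <- list(a = max(d$height_m) * 1.2, b = stats::median(d$dbh_cm))
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = d, start = start,
                      lower = c(1e-8, 1e-8)),
    error = function(e) stop("fit_height_model: fit failure: ",
                             conditionMessage(e), call. = FALSE))
  pred <- stats::predict(fit)
  ss <- sum((d$height_m - mean(d$height_m))^2)
  structure(list(coefficients = stats::coef(fit),
                 r2 = if (ss > 0) 1 - sum((d$height_m - pred)^2) / ss else NA,
                 sigma = stats::sigma(fit),
                 fitted = pred, residuals = d$height_m - pred,
                 data = d, nls = fit),
            class = "height_fit")
}

#' @export
print.height_fit <- function(x, digits = 4, ...) {
  cat("Saturating diameter-height model: H = a * DBH / (b + DBH)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  r2 = %.3f, residual sd = %.3f m, n = %d\n",
              x$r2, x$sigma, nrow(x$data)))
  invisible(x)
}

#' @export
coef.height_fit <- function(object, ...) object$coefficients

#' @export
predict.height_fit <- function(object, newdata = NULL, ...) {
  dbh <- if (is.null(newdata)) object$data$dbh_cm else
    if (is.data.frame(newdata)) newdata$dbh_cm else newdata
  p <- object$coefficients
  unname(p["a"] * dbh / (p["b"] + dbh))
}

#' @export
residuals.height_fit <- function(object, ...) object$residuals
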