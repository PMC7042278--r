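# Independent brute-force implementations used as oracles. Deliberately
# written loop-by-loop, with no shared code with the package internals.

glk_brute <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in 2:n) {
    dx <- x[i] - x[i - 1]
    dy <- y[i] - y[i - 1]
    if ((dx > 0 && dy > 0) || (dx < 0 && dy < 0) || (dx == 0 && dy == 0)) {
      s <- s + 1
    } else if (dx == 0 || dy == 0) {
      s <- s + 0.5
    }
  }
  100 * s / (n - 1)
}

# centred 5-year moving average with clipped edge windows, by loops
ma5_brute <- function(w) {
  n <- length(w)
  out <- numeric(n)
  for (i in 1:n) {
    lo <- max(1, i - 2); hi <- min(n, i + 2)
    out[i] <- mean(w[lo:hi])
  }
  out
}

tbp_brute <- function(x, y) {
  tx <- log(x / ma5_brute(x))
  ty <- log(y / ma5_brute(y))
  n <- length(x)
  mx <- mean(tx); my <- mean(ty)
  r <- sum((tx - mx) * (ty - my)) /
    sqrt(sum((tx - mx)^2) * sum((ty - my)^2))
  r * sqrt((n - 2) / (1 - r^2))
}

ms_brute <- function(x) {
  acc <- 0
  for (i in 2:length(x))
    acc <- acc + abs(2 * (x[i] - x[i - 1]) / (x[i] + x[i - 1]))
  acc / (length(x) - 1)
}

pearson_brute <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    (sqrt(sum((x - mx)^2) / (length(x) - 1)) *
     sqrt(sum((y - my)^2) / (length(y) - 1)) * (length(x) - 1))
}

chisq_brute <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

anova_f_brute <- function(values, groups) {
  g <- unique(groups)
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (gi in g) {
    v <- values[groups == gi]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  (ssb / (length(g) - 1)) / (ssw / (length(values) - length(g)))
}

# random positive ring-width-like series
rand_widths <- function(n, mu = 2) mu * exp(stats::rnorm(n, 0, 0.4))

# small dated series around a planted common signal
make_signal_series <- function(n_trees, n_years, first_year = 1981,
                               signal_sd = 0.4, noise_sd = 0.1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(n_years, 0, signal_sd)
  lapply(seq_len(n_trees), function(i) {
    w <- 2 * exp(z + stats::rnorm(n_years, 0, noise_sd))
    ring_series(sprintf("S%02d", i), first_year = first_year, widths = w)
  })
}
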