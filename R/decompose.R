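## Seasonal-trend decomposition of monthly count series by iterated loess,
## and range-standardized seasonal profiles.

#' Extract one roost x stratum monthly series from a count table
#'
#' Builds a gap-explicit monthly series: every calendar month between the
#' roost's first and last observation appears once, with `NA` for months
#' not counted.
#'
#' @param table a [roost_counts] table.
#' @param roost roost label (use `"pooled"` after [pool_roosts()]).
#' @param stratum stratum column name.
#' @return data frame `(year, month, value)` of consecutive calendar
#'   months, with attributes `roost` and `stratum`; class `monthly_series`.
#' @export
monthly_series <- function(table, roost, stratum = "all_parrots") {
  stopifnot(inherits(table, "roost_counts"))
  if (!stratum %in% .strata_cols)
    stop_roostdemog(paste0("unknown stratum: ", stratum),
                    "roostdemog_argument_error")
  d <- table[table$roost == roost, ]
  if (nrow(d) == 0)
    stop_roostdemog(paste0("no records for roost ", roost),
                    "roostdemog_argument_error")
  y0 <- d$year[1]; m0 <- d$month[1]
  idx <- month_index(d$year, d$month, y0, m0)
  n <- max(idx) + 1L
  value <- rep(NA_real_, n)
  value[idx + 1L] <- d[[stratum]]
  cal <- month_shift(y0, m0, 0:(n - 1L))
  out <- data.frame(year = cal$year, month = cal$month, value = value)
  attr(out, "roost") <- roost
  attr(out, "stratum") <- stratum
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' Loess smoothing with tricube nearest-neighbour weights
#'
#' Local polynomial regression: at each target point the `q =
#' ceiling(span * n)` nearest neighbours are fit by weighted least squares
#' with tricube weights `w = (1 - (d / d_max)^3)^3`, where `d_max` is the
#' distance to the farthest included neighbour, and the local polynomial is
#' evaluated at the target. Degree 0 gives a running weighted mean, degree
#' 1 a running weighted line.
#'
#' @param t numeric predictor (time) coordinates.
#' @param y numeric responses, same length as `t`.
#' @param span fraction of points in each local window, in (0, 1].
#' @param degree local polynomial degree, 0 or 1.
#' @return fitted values at each `t`.
#' @examples
#' t <- 1:20
#' loess_smooth(t, 2 + 0.5 * t, span = 0.5)  # reproduces the line exactly
#' @export
loess_smooth <- function(t, y, span = 0.75, degree = 1) {
  stopifnot(length(t) == length(y), degree %in% c(0, 1),
            span > 0, span <= 1)
  n <- length(t)
  if (n < degree + 2)
    stop_roostdemog("loess_smooth() needs at least degree + 2 points",
                    "roostdemog_argument_error")
  q <- min(n, max(ceiling(span * n), degree + 2))
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(t - t[i])
    keep <- order(d)[seq_len(q)]
    dmax <- d[keep[q]]
    w <- if (dmax == 0) rep(1, q) else (1 - pmin(d[keep] / dmax, 1)^3)^3
    if (degree == 0) {
      fitted[i] <- sum(w * y[keep]) / sum(w)
    } else {
      x <- t[keep] - t[i]  # centred: intercept is the fitted value
      pos <- w > 0
      fit <- stats::lm.wfit(cbind(1, x[pos]), y[keep][pos], w[pos])
      fitted[i] <- fit$coefficients[1]
    }
  }
  fitted
}

#' Seasonal sub-series means
#'
#' The seasonal component of a monthly series: the mean of all January
#' values, all February values, and so on, centred so the twelve monthly
#' effects sum to zero (the level belongs to the trend, not the season).
#'
#' @param values numeric vector of (typically detrended) observations.
#' @param months calendar month (1-12) of each observation.
#' @return numeric vector of 12 zero-sum monthly effects.
#' @export
seasonal_subseries_means <- function(values, months) {
  stopifnot(length(values) == length(months))
  means <- vapply(1:12, function(m) {
    v <- values[months == m]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(means))
    stop_roostdemog(
      paste0("no observations for month(s): ",
             paste(month.abb[is.na(means)], collapse = ", ")),
      "roostdemog_coverage_error")
  means - mean(means)
}

#' Seasonal-trend decomposition of a monthly series by iterated loess
#'
#' Splits a monthly count series into three additive parts: a 12-periodic
#' seasonal component (sub-series means of the detrended data), a smooth
#' trend (loess of the deseasonalized data), and the remainder. Starting
#' from a flat trend at the series mean, the seasonal and trend steps are
#' alternated `n_iter` times; the remainder is the residual from seasonal
#' plus trend. Internal gaps are linearly interpolated before
#' decomposition and flagged; the remainder is reported missing there.
#'
#' @param series a [monthly_series], or data frame `(year, month, value)`.
#' @param span loess span for the trend; default `NULL` targets a window
#'   of 19 neighbours, the conventional trend window for period-12 series
#'   with a periodic seasonal.
#' @param n_iter number of seasonal/trend passes (default 2).
#' @param degree trend loess degree (default 1).
#' @return object of class `stl_decomposition`: a list with `components`
#'   (data frame `year, month, observed, filled, seasonal, trend,
#'   remainder, interpolated`), `seasonal_months` (the 12 zero-sum monthly
#'   effects), and `settings`.
#' @export
stl_decompose <- function(series, span = NULL, n_iter = 2, degree = 1) {
  stopifnot(is.data.frame(series),
            all(c("year", "month", "value") %in% names(series)))
  ## drop leading/trailing missing months; never extrapolate
  obs <- which(!is.na(series$value))
  if (length(obs) == 0)
    stop_roostdemog("series has no observations", "roostdemog_argument_error")
  series <- series[min(obs):max(obs), ]
  y_obs <- series$value
  n <- nrow(series)
  if (sum(!is.na(y_obs)) < 24)
    stop_roostdemog("decomposition needs at least 24 observations",
                    "roostdemog_argument_error")
  t <- seq_len(n) - 1
  interpolated <- is.na(y_obs)
  y <- y_obs
  if (any(interpolated))
    y[interpolated] <- stats::approx(t[!interpolated], y_obs[!interpolated],
                                     xout = t[interpolated])$y
  if (is.null(span)) span <- min(1, 19 / n)
  months <- series$month
  trend <- rep(mean(y), n)
  for (k in seq_len(n_iter)) {
    seas12 <- seasonal_subseries_means(y - trend, months)
    seasonal <- seas12[months]
    trend <- loess_smooth(t, y - seasonal, span = span, degree = degree)
  }
  remainder <- y - seasonal - trend
  remainder[interpolated] <- NA_real_
  comp <- data.frame(year = series$year, month = series$month,
                     observed = y_obs, filled = y, seasonal = seasonal,
                     trend = trend, remainder = remainder,
                     interpolated = interpolated)
  structure(list(components = comp, seasonal_months = seas12,
                 settings = list(span = span, n_iter = n_iter,
                                 degree = degree,
                                 roost = attr(series, "roost"),
                                 stratum = attr(series, "stratum"))),
            class = "stl_decomposition")
}

#' Range-standardize a seasonal component
#'
#' Rescales the twelve monthly seasonal effects to `[0, 1]` so roosts with
#' very different sizes can share one radial plot: the quietest month maps
#' to 0 and the busiest to 1.
#'
#' @param seasonal numeric vector of 12 seasonal effects (or an
#'   `stl_decomposition`, whose `seasonal_months` are used).
#' @return numeric vector of 12 values in `[0, 1]` named by month.
#' @export
range_standardize <- function(seasonal) {
  if (inherits(seasonal, "stl_decomposition"))
    seasonal <- seasonal$seasonal_months
  stopifnot(is.numeric(seasonal), length(seasonal) == 12)
  rng <- range(seasonal)
  if (diff(rng) == 0)
    stop_roostdemog("constant seasonal component cannot be range-standardized",
                    "roostdemog_degenerate_error")
  stats::setNames((seasonal - rng[1]) / diff(rng), month.abb)
}

#' @export
print.stl_decomposition <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Seasonal-trend decomposition (%s / %s): %d months, span %.3f, %d iteration(s)\n",
    s$roost %||% "?", s$stratum %||% "?", nrow(x$components), s$span,
    s$n_iter))
  cat("Seasonal monthly effects:\n")
  print(round(stats::setNames(x$seasonal_months, month.abb), 2), ...)
  invisible(x)
}
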