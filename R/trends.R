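## Long-term trend fits: simple regression of a monthly series on elapsed
## months, and grouped (roost + time) ANCOVA of family-flock responses.

#' Linear trend of a monthly series
#'
#' Ordinary least squares of the series values on elapsed months since the
#' series' first observation (0-based), optionally with a raw-permutation
#' p-value for the slope. The per-year slope is `12 *` the per-month slope.
#'
#' @param series a [monthly_series] or data frame `(year, month, value)`.
#' @param permute logical; attach a permutation p-value.
#' @param n_perm,seed passed to [permutation_test()] when `permute`.
#' @return object of class `trend_fit`: list with `slope` (per month),
#'   `intercept`, `slope_per_year`, `F`, `df` (numerator, denominator),
#'   `r_squared`, `n_obs`, `p_classical`, and `p_perm` (`NA` unless
#'   permuted).
#' @export
linear_trend <- function(series, permute = FALSE, n_perm = 4999,
                         seed = NULL) {
  stopifnot(is.data.frame(series),
            all(c("year", "month", "value") %in% names(series)))
  first <- which(!is.na(series$value))[1]
  if (is.na(first))
    stop_roostdemog("series has no observations", "roostdemog_argument_error")
  t <- month_index(series$year, series$month,
                   series$year[first], series$month[first])
  keep <- !is.na(series$value)
  d <- data.frame(t = t[keep], value = series$value[keep])
  if (nrow(d) < 3)
    stop_roostdemog("linear_trend() needs at least 3 observations",
                    "roostdemog_argument_error")
  if (length(unique(d$t)) < 2)
    stop_roostdemog("time index is constant", "roostdemog_design_error")
  fit <- stats::lm(value ~ t, data = d)
  terms <- fit_linear_model(value ~ t, d)
  p_perm <- NA_real_
  if (permute) {
    pt <- permutation_test(value ~ t, d, n_perm = n_perm, seed = seed,
                           scheme = "raw")
    p_perm <- pt$table$p_perm[1]
  }
  structure(list(slope = unname(stats::coef(fit)["t"]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_per_year = 12 * unname(stats::coef(fit)["t"]),
                 F = terms$table$F[1],
                 df = c(terms$table$df[1], terms$df_residual),
                 r_squared = terms$r_squared,
                 n_obs = terms$n_obs,
                 p_classical = terms$table$p_classical[1],
                 p_perm = p_perm,
                 n_perm = if (permute) n_perm else NA_integer_,
                 seed = seed),
            class = "trend_fit")
}

#' Roost-adjusted trend of family-flock responses
#'
#' Derives a per-record response from the family-flock stratum — either
#' the number of family flocks or the mean fledglings per flock
#' ([family_flock_stats()]) — and fits a permutation ANCOVA
#' `response ~ roost + time` after checking slope parallelism with
#' [ancova_with_parallelism()]. Time is months elapsed since the first
#' included record, shared across roosts. Records where the response is
#' undefined (no family flocks, for the per-flock mean) are dropped.
#'
#' @param table a [roost_counts] table.
#' @param response `"n_family_flocks"` or `"mean_fledglings_per_flock"`.
#' @param roosts roost labels to include; default all. (In monitoring
#'   applications a roost known to be collapsing is usually excluded so
#'   its disappearance does not masquerade as a demographic trend.)
#' @param alpha parallelism threshold for the interaction check.
#' @param n_perm,seed passed to the permutation tests.
#' @return list of class `grouped_trend`: the [ancova_with_parallelism()]
#'   result plus `slope` (common time slope, per month; `NA` when slopes
#'   are non-parallel), `slope_per_year`, `response`, `n_obs`, and
#'   `overall_mean` of the response.
#' @export
grouped_trend <- function(table, response = c("n_family_flocks",
                                              "mean_fledglings_per_flock"),
                          roosts = NULL, alpha = 0.05, n_perm = 4999,
                          seed = NULL) {
  stopifnot(inherits(table, "roost_counts"))
  response <- match.arg(response)
  if (!is.null(roosts)) table <- table[table$roost %in% roosts, ]
  if (nrow(table) == 0)
    stop_roostdemog("no records left after roost selection",
                    "roostdemog_argument_error")
  ff <- family_flock_stats(table$family_flock_birds, table$fledglings)
  d <- data.frame(roost = factor(table$roost), year = table$year,
                  month = table$month, value = ff[[response]])
  d <- d[!is.na(d$value), ]
  t0 <- order(d$year, d$month)[1]
  d$time <- month_index(d$year, d$month, d$year[t0], d$month[t0])
  res <- ancova_with_parallelism(value ~ roost + time + roost:time, d,
                                 alpha = alpha, n_perm = n_perm, seed = seed)
  slope <- NA_real_
  if (res$slopes == "parallel-slopes") {
    fit <- stats::lm(value ~ roost + time, data = d)
    slope <- unname(stats::coef(fit)["time"])
  }
  res$slope <- slope
  res$slope_per_year <- 12 * slope
  res$response <- response
  res$n_obs <- nrow(d)
  res$overall_mean <- mean(d$value)
  class(res) <- c("grouped_trend", class(res))
  res
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Linear trend: slope %.4g per month (%.4g per year), F(%d, %d) = %.4g, r2 = %.3f, n = %d\n",
    x$slope, x$slope_per_year, x$df[1], x$df[2], x$F, x$r_squared, x$n_obs))
  cat(sprintf("  p (classical) = %.4g", x$p_classical))
  if (!is.na(x$p_perm))
    cat(sprintf("; p (permutation, %d perms) = %.4g", x$n_perm, x$p_perm))
  cat("\n")
  invisible(x)
}
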