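# A deterministic monthly series builder: year/month calendar from Jan 2000.
make_series <- function(values, start_month = 1) {
  n <- length(values)
  m0 <- start_month - 1 + seq_len(n) - 1
  data.frame(year = 2000 + m0 %/% 12, month = m0 %% 12 + 1, value = values)
}

test_that("loess_smooth matches a per-point weighted least squares oracle", {
  set.seed(9)
  for (case in 1:8) {
    n <- sample(9:40, 1)
    t <- sort(runif(n, 0, 30))
    y <- sin(t / 3) + rnorm(n, sd = 0.3)
    span <- runif(1, 0.3, 1)
    degree <- sample(0:1, 1)
    got <- loess_smooth(t, y, span = span, degree = degree)
    want <- vapply(t, function(t0)
      oracle_loess_point(t, y, t0, span, degree), numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("loess_smooth reproduces lines and constants exactly", {
  t <- 1:20
  y <- 2 - 0.7 * t
  for (span in c(0.3, 0.5, 1)) {
    expect_equal(loess_smooth(t, y, span = span, degree = 1), y,
                 tolerance = 1e-12)
  }
  expect_equal(loess_smooth(t, rep(3, 20), span = 0.4, degree = 0),
               rep(3, 20))
  expect_error(loess_smooth(1:2, 1:2, degree = 1),
               class = "roostdemog_argument_error")
})

test_that("seasonal sub-series means recover periodic patterns, centred", {
  s <- c(3, 1, -2, -4, -1, 5, 6, 2, -3, -2, -1, -4)
  s <- s - mean(s)
  months <- rep(1:12, 2)
  expect_equal(seasonal_subseries_means(s[months], months), s)
  expect_equal(seasonal_subseries_means(rep(7, 24), months), rep(0, 12))

  # group-by-month mean oracle on a noisy 36-month series
  set.seed(4)
  months3 <- rep(1:12, 3)
  v <- s[months3] + rnorm(36, sd = 0.1)
  want <- as.numeric(tapply(v, months3, mean))
  want <- want - mean(want)
  expect_equal(seasonal_subseries_means(v, months3), want)
  expect_error(seasonal_subseries_means(1:11, 1:11),
               class = "roostdemog_coverage_error")
})

test_that("decomposition is additive and recovers noiseless structure", {
  s <- c(3, 1, -2, -4, -1, 5, 6, 2, -3, -2, -1, -4)
  s <- s - mean(s)
  n <- 48
  mon <- rep(1:12, length.out = n)
  y <- 10 + 0.5 * (0:(n - 1)) + s[mon]
  dec <- stl_decompose(make_series(y))

  comp <- dec$components
  # exact additivity at observed points
  expect_equal(comp$seasonal + comp$trend + comp$remainder, comp$filled)
  # seasonal strictly 12-periodic and zero-sum
  expect_equal(comp$seasonal, dec$seasonal_months[comp$month])
  expect_equal(sum(dec$seasonal_months), 0, tolerance = 1e-10)
  # components close to the generating structure at default settings
  expect_lt(max(abs(comp$remainder)), 0.05 * diff(range(y)))
  slope <- coef(lm(comp$trend ~ seq_len(n)))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.02)

  # iterated to convergence the noiseless case is reproduced to 1e-6
  dec15 <- stl_decompose(make_series(y), n_iter = 15)
  expect_lt(max(abs(dec15$components$remainder[13:36])), 1e-6)
  expect_lt(max(abs(dec15$seasonal_months - s)), 1e-5)
})

test_that("constant series decompose to zero seasonal and flat trend", {
  dec <- stl_decompose(make_series(rep(11, 30)))
  expect_equal(dec$seasonal_months, rep(0, 12), tolerance = 1e-12)
  expect_equal(dec$components$trend, rep(11, 30), tolerance = 1e-12)
  expect_equal(dec$components$remainder, rep(0, 30), tolerance = 1e-12)
})

test_that("adding a constant moves into the trend, not the seasonal", {
  set.seed(2)
  y <- 50 + rnorm(36, sd = 5) + rep(c(-3, 3), length.out = 36)
  d1 <- stl_decompose(make_series(y))
  d2 <- stl_decompose(make_series(y + 100))
  expect_equal(d1$seasonal_months, d2$seasonal_months, tolerance = 1e-9)
  expect_equal(d2$components$trend - d1$components$trend, rep(100, 36),
               tolerance = 1e-9)
})

test_that("internal gaps are interpolated and flagged, edges dropped", {
  y <- 20 + sin(2 * pi * (0:35) / 12) * 4
  y[c(10, 20)] <- NA
  ser <- make_series(c(NA, y, NA))  # leading/trailing missing months
  dec <- stl_decompose(ser)
  comp <- dec$components
  expect_equal(nrow(comp), 36)
  expect_equal(which(comp$interpolated), c(10, 20))
  expect_true(all(is.na(comp$remainder[c(10, 20)])))
  expect_true(all(!is.na(comp$remainder[-c(10, 20)])))
  # interpolation is linear between the observed neighbours
  expect_equal(comp$filled[10], mean(y[c(9, 11)]))
  expect_error(stl_decompose(make_series(y[1:20])),
               class = "roostdemog_argument_error")
})

test_that("seasonal recovery from the stochastic generator is faithful", {
  cfg <- synthetic_config()
  rec <- vapply(1:20, function(r) {
    tab <- generate_roost_counts(cfg, seed = 100 + r)
    dec <- stl_decompose(monthly_series(pool_roosts(tab), "pooled",
                                        "pairs"))
    c(hits = sum(abs(rank(dec$seasonal_months) -
                       rank(cfg$templates$pairs)) <= 1),
      rho = cor(dec$seasonal_months, cfg$templates$pairs,
                method = "spearman"))
  }, numeric(2))
  # the recovered profile puts at least 10 of 12 months within one rank
  # position of the template, and the ordering correlates strongly
  expect_gte(median(rec["hits", ]), 10)
  expect_true(all(rec["rho", ] > 0.9))

  tab <- generate_roost_counts(cfg, seed = 5)
  dec <- stl_decompose(monthly_series(pool_roosts(tab), "pooled", "pairs"))
  expect_gt(cor(dec$seasonal_months, cfg$templates$pairs), 0.9)
})

test_that("components agree with the reference periodic STL implementation", {
  set.seed(10)
  s <- c(3, 1, -2, -4, -1, 5, 6, 2, -3, -2, -1, -4)
  s <- s - mean(s)
  y <- 100 + 0.8 * (0:59) + s[rep(1:12, 5)] + rnorm(60, sd = 2)
  ref <- stats::stl(stats::ts(y, frequency = 12), s.window = "periodic")
  ser <- make_series(y)
  dec <- stl_decompose(ser)
  expect_gt(cor(dec$seasonal_months,
                as.numeric(ref$time.series[1:12, "seasonal"])), 0.999)
  expect_lt(max(abs(dec$components$trend -
                      as.numeric(ref$time.series[, "trend"]))),
            0.05 * sd(y))
})

test_that("range standardization maps the seasonal to [0, 1] exactly", {
  s <- c(-1, 0, 0.5, 1, 2, 3, 2.5, 0.2, -0.5, -0.9, 0.1, 0.3)
  p <- range_standardize(s)
  expect_equal(min(p), 0)
  expect_equal(max(p), 1)
  expect_equal(unname(p), (s - min(s)) / diff(range(s)))
  expect_equal(unname(range_standardize(unname(p))), unname(p))  # idempotent
  expect_error(range_standardize(rep(0, 12)),
               class = "roostdemog_degenerate_error")
})
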