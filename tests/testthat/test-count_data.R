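test_that("CSV reading accepts canonical and deposited dialects identically", {
  tab <- toy_counts()
  canon <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(tab), canon, row.names = FALSE)
  dep <- tempfile(fileext = ".csv")
  d <- as.data.frame(tab)
  names(d) <- c("Roost", "year", "month", "all.parrots", "singles", "pairs",
                "fledglings", "family.flocks", "large.flocks")
  write.csv(d, dep, row.names = FALSE)

  from_canon <- read_counts(canon)
  from_dep <- read_counts(dep, dialect = "deposited")
  expect_s3_class(from_canon, "roost_counts")
  expect_equal(nrow(from_canon), 8)
  expect_equal(from_canon, from_dep)
  expect_equal(from_canon, read_counts(dep))  # auto dialect

  # "-" and empty cells become NA; junk warns and becomes NA
  d$singles[1] <- "-"
  d$pairs[2] <- ""
  d$fledglings[3] <- "x?"
  write.csv(d, dep, row.names = FALSE, quote = FALSE)
  expect_warning(got <- read_counts(dep), "unparseable")
  expect_true(is.na(got$singles[got$month == 6 & got$roost == "A"]))

  # a missing mandatory column is a format error naming it
  d2 <- as.data.frame(tab)
  d2$singles <- NULL
  write.csv(d2, canon, row.names = FALSE)
  expect_error(read_counts(canon), "singles",
               class = "roostdemog_format_error")
})

test_that("duplicate roost x month records are rejected", {
  d <- as.data.frame(toy_counts())
  expect_error(as_roost_counts(rbind(d, d[1, ])),
               class = "roostdemog_duplicate_error")
})

test_that("validate_counts reports identity and flock-count violations", {
  # consistent record: 2 + 2*3 + 8 + 10 = 26, implied 3 family flocks
  ok <- as_roost_counts(data.frame(
    roost = "r", year = 2005, month = 6, all_parrots = 26, singles = 2,
    pairs = 3, fledglings = 2, family_flock_birds = 8,
    large_flock_birds = 10))
  expect_equal(nrow(validate_counts(ok)), 0)

  bad_total <- ok
  bad_total$all_parrots <- 25
  v <- validate_counts(bad_total)
  expect_equal(v$rule, "stratification_identity")

  bad_flocks <- ok
  bad_flocks$fledglings <- 3  # (8 - 3) / 2 = 2.5 flocks
  bad_flocks$all_parrots <- 26
  v <- validate_counts(bad_flocks)
  expect_true("family_flocks_integer" %in% v$rule)

  neg <- ok
  neg$singles <- -1
  expect_true("nonnegative" %in% validate_counts(neg)$rule)

  # strict mode enforces the 3-6 birds and 1-4 young per flock bounds
  expect_true("flock_size_bounds" %in% validate_counts(ok, strict = TRUE)$rule)
  strict_ok <- ok
  strict_ok$fledglings <- 4  # 2 flocks of (8+4)... recompute: (12-4)/2
  strict_ok$family_flock_birds <- 12
  strict_ok$all_parrots <- 30
  expect_equal(nrow(validate_counts(strict_ok, strict = TRUE)), 0)
})

test_that("family_flock_stats derives flock counts and mean brood size", {
  expect_equal(family_flock_stats(10, 4),
               data.frame(n_family_flocks = 3,
                          mean_fledglings_per_flock = 4 / 3))
  expect_equal(family_flock_stats(6, 2),
               data.frame(n_family_flocks = 2,
                          mean_fledglings_per_flock = 1))
  empty <- family_flock_stats(0, 0)
  expect_equal(empty$n_family_flocks, 0)
  expect_true(is.na(empty$mean_fledglings_per_flock))
  expect_error(family_flock_stats(7, 2), class = "roostdemog_invariant_error")
  expect_error(family_flock_stats(3, 5), class = "roostdemog_invariant_error")
})

test_that("pool_roosts sums strata over reporting roosts only", {
  tab <- toy_counts()
  pooled <- pool_roosts(tab)
  expect_equal(unique(pooled$roost), "pooled")
  expect_equal(pooled$all_parrots[pooled$month == 6], 300 + 400)
  expect_equal(pooled$pairs[pooled$month == 7], 110 + 130)

  # a roost missing a stratum contributes nothing, not zero
  tab2 <- as.data.frame(tab)
  tab2$singles[tab2$roost == "B" & tab2$month == 6] <- NA
  pooled2 <- pool_roosts(as_roost_counts(tab2))
  expect_equal(pooled2$singles[pooled2$month == 6], 4)
  # a stratum missing everywhere stays missing
  tab2$singles[tab2$month == 7] <- NA
  pooled3 <- pool_roosts(as_roost_counts(tab2))
  expect_true(is.na(pooled3$singles[pooled3$month == 7]))
})

test_that("monthly_median_table gives per-roost medians plus a pooled row", {
  tab <- as_roost_counts(data.frame(
    roost = "A", year = rep(2004:2006, each = 1), month = 6,
    all_parrots = c(100, 300, 200), singles = 1, pairs = 10,
    fledglings = 2, family_flock_birds = 6, large_flock_birds = NA))
  mm <- monthly_median_table(tab)
  expect_equal(mm$Jun[mm$roost == "A"], 200)
  expect_true(all(is.na(mm$Jan)))

  # single roost: pooled row equals the per-roost row
  expect_equal(unname(unlist(mm[mm$roost == "pooled", month.abb])),
               unname(unlist(mm[mm$roost == "A", month.abb])))
  expect_error(monthly_median_table(tab, "nonexistent"),
               class = "roostdemog_argument_error")
})

test_that("median_iqr matches a sort-based quantile oracle on short samples", {
  set.seed(42)
  grid <- c(-3, -1.5, 0, 0.25, 1, 2.5, 7, 10)
  for (n in 1:8) {
    for (rep in 1:25) {
      x <- sample(grid, n, replace = TRUE)
      got <- median_iqr(x)
      expect_equal(got$median, oracle_quantile(x, 0.5))
      expect_equal(got$iqr,
                   oracle_quantile(x, 0.75) - oracle_quantile(x, 0.25))
      expect_equal(got$n, n)
    }
  }
  expect_equal(median_iqr(5), list(median = 5, iqr = 0, n = 1))
  expect_error(median_iqr(c(NA_real_, NA_real_)),
               class = "roostdemog_argument_error")
})

test_that("every generated table satisfies the stratification identity", {
  for (seed in 1:5) {
    tab <- generate_roost_counts(synthetic_config(), seed = seed)
    expect_equal(nrow(validate_counts(tab)), 0)
    with(tab, expect_equal(all_parrots,
                           singles + 2 * pairs + family_flock_birds +
                             large_flock_birds))
  }
})
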