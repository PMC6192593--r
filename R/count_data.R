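## Flock-size-stratified monthly roost counts: reading, validation, pooling
## and median/IQR summaries.

#' @name roost_counts
#' @title Stratified roost-count tables
#'
#' @description
#' A `roost_counts` table is a data frame with one row per roost x month
#' and the columns
#' `roost`, `year`, `month`, `all_parrots`, `singles`, `pairs`,
#' `fledglings`, `family_flock_birds`, `large_flock_birds`.
#' Counts are birds except `pairs`, which is a count of dyads (units of two
#' paired birds). `family_flock_birds` is all individuals arriving in flocks
#' of three to six; `fledglings` is the same birds after discounting the two
#' parental birds of each family flock, so the number of family flocks is
#' the derived quantity `(family_flock_birds - fledglings) / 2`.
#' `NA` marks a stratum not recorded that month.
#'
#' When every stratum is present the strata tile the total:
#' `all_parrots = singles + 2 * pairs + family_flock_birds +
#' large_flock_birds`.
NULL

.strata_cols <- c("all_parrots", "singles", "pairs", "fledglings",
                  "family_flock_birds", "large_flock_birds")
.key_cols <- c("roost", "year", "month")

## Header aliases: deposited-dialect names (dotted, as in the public data
## repository) and a few common variants, mapped onto canonical names.
.dialect_map <- c(
  "roost" = "roost", "Roost" = "roost",
  "year" = "year", "Year" = "year",
  "month" = "month", "Month" = "month",
  "all_parrots" = "all_parrots", "all.parrots" = "all_parrots",
  "singles" = "singles", "Singles" = "singles",
  "pairs" = "pairs", "Pairs" = "pairs",
  "fledglings" = "fledglings", "Fledglings" = "fledglings",
  "family_flock_birds" = "family_flock_birds",
  "family.flocks" = "family_flock_birds",
  "large_flock_birds" = "large_flock_birds",
  "large.flocks" = "large_flock_birds"
)

#' Construct a validated roost-count table
#'
#' @param x data frame with canonical columns (see [roost_counts]).
#' @return `x`, key-sorted, with class `roost_counts`.
#' @export
as_roost_counts <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(c(.key_cols, .strata_cols), names(x))
  if (length(missing_cols) > 0)
    stop_roostdemog(
      paste0("missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      "roostdemog_format_error")
  x$roost <- as.character(x$roost)
  x$year <- as.integer(x$year)
  x$month <- as.integer(x$month)
  if (anyNA(x$year) || anyNA(x$month) || any(x$month < 1 | x$month > 12))
    stop_roostdemog("year/month must be complete, with month in 1..12",
                    "roostdemog_format_error")
  for (cl in .strata_cols) x[[cl]] <- as.numeric(x[[cl]])
  key <- paste(x$roost, x$year, x$month)
  if (anyDuplicated(key))
    stop_roostdemog(
      paste0("duplicate roost x month record(s): ",
             paste(unique(key[duplicated(key)]), collapse = "; ")),
      "roostdemog_duplicate_error")
  x <- x[order(x$roost, x$year, x$month), c(.key_cols, .strata_cols)]
  rownames(x) <- NULL
  class(x) <- c("roost_counts", "data.frame")
  x
}

#' Read a stratified roost-count table from CSV
#'
#' Accepts either canonical headers (`roost, year, month, all_parrots,
#' singles, pairs, fledglings, family_flock_birds, large_flock_birds`) or
#' the deposited dialect used by the public five-roost Pantanal dataset
#' (`Roost, all.parrots, singles, pairs, fledglings, family.flocks,
#' large.flocks`). Empty cells and `"-"` become `NA`; any other
#' unparseable cell becomes `NA` with a warning.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect `"auto"` (default) resolves each header through the alias
#'   table; `"canonical"` and `"deposited"` restrict to one naming scheme.
#' @return a [roost_counts] table.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "roost,year,month,all_parrots,singles,pairs,fledglings,family_flock_birds,large_flock_birds",
#'   "1,2005,6,120,4,40,6,16,20",
#'   "1,2005,7,110,2,38,8,20,12"), csv)
#' read_counts(csv)
#' @export
read_counts <- function(path, dialect = c("auto", "canonical", "deposited")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("", "-", "NA"))
  nm <- names(raw)
  allowed <- switch(dialect,
    auto = .dialect_map,
    canonical = .dialect_map[names(.dialect_map) == .dialect_map],
    deposited = .dialect_map[c("Roost", "roost", "year", "month",
                               "all.parrots", "singles", "pairs",
                               "fledglings", "family.flocks",
                               "large.flocks")]
  )
  mapped <- allowed[nm]
  keep <- !is.na(mapped)
  raw <- raw[keep]
  names(raw) <- mapped[keep]
  for (cl in intersect(.strata_cols, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- !is.na(raw[[cl]]) & is.na(parsed)
    if (any(bad))
      warning(sprintf("column '%s': %d unparseable cell(s) set to NA",
                      cl, sum(bad)), call. = FALSE)
    raw[[cl]] <- parsed
  }
  as_roost_counts(raw)
}

#' Check the flock-size stratification identities of a count table
#'
#' Reports, without modifying the table, every record that violates the
#' count-data model: negative or non-integer counts; a total that does not
#' equal `singles + 2*pairs + family_flock_birds + large_flock_birds`; a
#' family-flock stratum whose implied flock count
#' `(family_flock_birds - fledglings)/2` is negative or fractional, or
#' member birds recorded with no implied flock. With `strict = TRUE` the
#' three-to-six flock-size bounds are also enforced: `3n <=
#' family_flock_birds <= 6n` and one to four fledglings per flock. The
#' strict bounds are optional because observers may record family flocks
#' whose young have merged into other flocks, leaving fewer than one
#' fledgling per flock on paper.
#'
#' @param table a [roost_counts] table.
#' @param strict logical; also enforce per-flock size bounds.
#' @return data frame of violations with columns `roost`, `year`, `month`,
#'   `rule`, `detail`; zero rows when the table is clean.
#' @export
validate_counts <- function(table, strict = FALSE) {
  stopifnot(inherits(table, "roost_counts"))
  out <- list()
  add <- function(i, rule, detail) {
    out[[length(out) + 1L]] <<- data.frame(
      roost = table$roost[i], year = table$year[i], month = table$month[i],
      rule = rule, detail = detail, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    vals <- unlist(r[.strata_cols])
    obs <- vals[!is.na(vals)]
    if (any(obs < 0))
      add(i, "nonnegative", paste0(names(obs)[obs < 0][1], " < 0"))
    if (any(obs != round(obs)))
      add(i, "integer", paste0(names(obs)[obs != round(obs)][1],
                               " not integer-valued"))
    if (!anyNA(vals)) {
      total <- r$singles + 2 * r$pairs + r$family_flock_birds +
        r$large_flock_birds
      if (!isTRUE(all.equal(total, r$all_parrots)))
        add(i, "stratification_identity",
            sprintf("strata sum %g != all_parrots %g", total, r$all_parrots))
    }
    if (!is.na(r$family_flock_birds) && !is.na(r$fledglings)) {
      n2 <- r$family_flock_birds - r$fledglings
      if (n2 < 0 || n2 %% 2 != 0) {
        add(i, "family_flocks_integer",
            sprintf("(family_flock_birds - fledglings)/2 = %g not a non-negative integer",
                    n2 / 2))
      } else {
        n <- n2 / 2
        if (n == 0 && r$family_flock_birds > 0)
          add(i, "family_flocks_integer",
              "family-flock birds recorded but implied flock count is 0")
        if (strict && n > 0) {
          if (r$family_flock_birds < 3 * n || r$family_flock_birds > 6 * n)
            add(i, "flock_size_bounds",
                sprintf("%g birds in %g flocks outside 3-6 per flock",
                        r$family_flock_birds, n))
          else if (r$fledglings / n < 1 || r$fledglings / n > 4)
            add(i, "fledglings_per_flock",
                sprintf("%g fledglings in %g flocks outside 1-4 per flock",
                        r$fledglings, n))
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(roost = character(), year = integer(),
                      month = integer(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Family-flock count and mean fledglings per flock
#'
#' Family flocks are a parental pair plus its fledged young, so the number
#' of flocks behind a record is `(family_flock_birds - fledglings) / 2` and
#' the mean brood size still flying with the parents is
#' `fledglings / n_family_flocks` (undefined when there are no flocks).
#'
#' @param family_flock_birds,fledglings numeric vectors (recycled).
#' @return data frame with columns `n_family_flocks` and
#'   `mean_fledglings_per_flock` (`NA` where inputs are missing or no
#'   flocks were seen).
#' @examples
#' family_flock_stats(10, 4)   # 3 flocks, 1.33 fledglings per flock
#' @export
family_flock_stats <- function(family_flock_birds, fledglings) {
  n2 <- family_flock_birds - fledglings
  bad <- !is.na(n2) & (n2 < 0 | n2 %% 2 != 0)
  if (any(bad))
    stop_roostdemog(
      "inconsistent inputs: (family_flock_birds - fledglings) must be a non-negative even number",
      "roostdemog_invariant_error")
  n <- n2 / 2
  mean_fl <- ifelse(!is.na(n) & n > 0, fledglings / n, NA_real_)
  data.frame(n_family_flocks = n, mean_fledglings_per_flock = mean_fl)
}

#' Pool counts over roosts
#'
#' Sums each stratum across all roosts reporting in a given month. A pooled
#' stratum is `NA` only when every roost is missing it that month; roosts
#' not monitored in a month simply do not contribute.
#'
#' @param table a [roost_counts] table.
#' @return a [roost_counts] table with a single roost labelled `"pooled"`.
#' @export
pool_roosts <- function(table) {
  stopifnot(inherits(table, "roost_counts"), nrow(table) > 0)
  key <- interaction(table$year, table$month, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    sums <- vapply(.strata_cols, function(cl) {
      v <- table[[cl]][idx]
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }, numeric(1))
    cbind(data.frame(roost = "pooled", year = table$year[idx][1],
                     month = table$month[idx][1]),
          as.data.frame(as.list(sums)))
  })
  as_roost_counts(do.call(rbind, rows))
}

#' Median and interquartile range of a sample
#'
#' Central tendency and spread for count and percentage data, which are
#' seldom normally distributed. Quartiles use linear-interpolation sample
#' quantiles with plotting position `h = (n - 1) p` (the default sample
#' quantile definition in most statistical software), the convention under
#' which the published annual summary tables are exactly reproducible.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return list with elements `median`, `iqr` and `n` (non-missing count).
#' @examples
#' median_iqr(c(2.4, 1.3, 3.2, 2.6, 2.7))  # median 2.6, IQR 0.3
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop_roostdemog("median_iqr() needs at least one non-missing value",
                    "roostdemog_argument_error")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], iqr = q[3] - q[1], n = length(values))
}

#' Median monthly counts by roost and calendar month
#'
#' For one stratum, tabulates the median over years of each roost's counts
#' in each calendar month, plus a pooled row summing the roosts before
#' taking medians. This is the table used to ask whether roost attendance
#' has an annual rhythm and when each roost peaks.
#'
#' @param table a [roost_counts] table.
#' @param stratum one of `all_parrots`, `singles`, `pairs`, `fledglings`,
#'   `family_flock_birds`, `large_flock_birds`.
#' @param pooled logical; append the pooled-roost row (default `TRUE`).
#' @return data frame with a `roost` column and one column per calendar
#'   month (`Jan` ... `Dec`); cells with no observations are `NA`.
#' @export
monthly_median_table <- function(table, stratum = "all_parrots",
                                 pooled = TRUE) {
  stopifnot(inherits(table, "roost_counts"))
  if (!stratum %in% .strata_cols)
    stop_roostdemog(paste0("unknown stratum: ", stratum),
                    "roostdemog_argument_error")
  tabs <- list(table)
  if (pooled) tabs <- c(tabs, list(pool_roosts(table)))
  rows <- lapply(tabs, function(tb) {
    do.call(rbind, lapply(split(tb, tb$roost), function(d) {
      med <- vapply(1:12, function(m) {
        v <- d[[stratum]][d$month == m]
        v <- v[!is.na(v)]
        if (length(v) == 0) NA_real_ else stats::median(v)
      }, numeric(1))
      cbind(data.frame(roost = d$roost[1]),
            stats::setNames(as.data.frame(as.list(med)), month.abb))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.roost_counts <- function(x, ...) {
  cat(sprintf("Stratified roost counts: %d record(s), %d roost(s), %d-%d\n",
              nrow(x), length(unique(x$roost)), min(x$year), max(x$year)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}
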