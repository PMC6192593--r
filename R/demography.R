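## Annual stratified summaries and the singleton/fledgling demographic
## estimators: breeding effort, expected recruitment, post-fledging loss.

#' Annual stratified summary for one roost and year
#'
#' Summarizes a roost-year by the windows that track the breeding cycle:
#' roost attendance peaks in June--July (the pre-reproductive maximum, used
#' as the population denominator), while singletons peak in August--
#' September, when one member of each incubating pair overnights at the
#' nest. Each window statistic is the mean of the available months.
#'
#' @param table a [roost_counts] table.
#' @param roost roost label.
#' @param year calendar year.
#' @return list with `roost`, `year`, `all_parrots` (mean Jun--Jul total),
#'   `singles_pct` (mean Aug--Sep singletons as % of `all_parrots`),
#'   `paired_pct` (mean Jun--Jul paired birds, `2 * pairs`, as %),
#'   `fledglings_pct` (mean Jun--Jul fledglings as %); `NA` where the
#'   window was not observed.
#' @export
annual_summary <- function(table, roost, year) {
  stopifnot(inherits(table, "roost_counts"))
  d <- table[table$roost == roost & table$year == year, ]
  win_mean <- function(col, months) {
    v <- d[[col]][d$month %in% months]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  denom <- win_mean("all_parrots", 6:7)
  if (is.na(denom))
    stop_roostdemog(
      sprintf("roost %s, %d: no June-July total available as denominator",
              roost, year),
      "roostdemog_denominator_error")
  pct <- function(x) if (is.na(x)) NA_real_ else 100 * x / denom
  list(roost = roost, year = year,
       all_parrots = denom,
       singles_pct = pct(win_mean("singles", 8:9)),
       paired_pct = pct(2 * win_mean("pairs", 6:7)),
       fledglings_pct = pct(win_mean("fledglings", 6:7)))
}

#' Annual stratified summary table with medians and IQRs
#'
#' Builds the roost-by-year grid of annual summaries ([annual_summary()]),
#' one row per roost x stratum with a column per year plus `median` and
#' `iqr` over the years with a defined value. A pooled block
#' (roosts summed via [pool_roosts()]) is appended. Roost-years whose
#' June--July denominator was not observed are left missing, not
#' zero-filled, and excluded from the medians.
#'
#' @param table a [roost_counts] table.
#' @param pooled logical; append the pooled-roost block (default `TRUE`).
#' @return data frame with columns `roost`, `stratum`, one column per
#'   year, `median`, `iqr`; strata are `all_parrots`, `singles_pct`,
#'   `paired_pct`, `fledglings_pct`.
#' @export
summary_table <- function(table, pooled = TRUE) {
  stopifnot(inherits(table, "roost_counts"))
  tabs <- list(table)
  if (pooled) tabs <- c(tabs, list(pool_roosts(table)))
  years <- sort(unique(table$year))
  strata <- c("all_parrots", "singles_pct", "paired_pct", "fledglings_pct")
  out <- list()
  for (tb in tabs) {
    for (r in unique(tb$roost)) {
      vals <- sapply(years, function(yr) {
        s <- tryCatch(annual_summary(tb, r, yr),
                      roostdemog_denominator_error = function(e) NULL)
        if (is.null(s)) rep(NA_real_, 4)
        else unlist(s[strata])
      })
      rownames(vals) <- strata
      for (st in strata) {
        v <- vals[st, ]
        mi <- if (all(is.na(v))) list(median = NA_real_, iqr = NA_real_)
              else median_iqr(v)
        row <- data.frame(roost = r, stratum = st, stringsAsFactors = FALSE)
        row[paste0("y", years)] <- as.list(v)
        row$median <- mi$median
        row$iqr <- mi$iqr
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Minimum proportion of pairs attempting to breed
#'
#' During incubation one member of each breeding pair stays at the nest
#' overnight while the other roosts alone, so the August--September
#' singleton percentage of the June--July roosting maximum is a minimum
#' estimate of the fraction of the roosting population attempting to
#' reproduce that year.
#'
#' @param summary an [annual_summary()] result, or a singleton percentage.
#' @return fraction in `[0, 1]` (`NA` propagates).
#' @export
breeding_attempt_proportion <- function(summary) {
  pct <- if (is.list(summary)) summary$singles_pct else summary
  pct / 100
}

#' Expected annual recruits from a stratum percentage
#'
#' Converts a median stratum percentage (singleton- or fledgling-based)
#' and the median June--July roosting maximum into whole birds recruited
#' per year: `round(pct/100 * all_parrots * fledge_rate)`. `fledge_rate`
#' scales pairs attempting to breed into young fledged; the default 1.0
#' reflects field estimates of 0.9--0.95 young fledged per laying female
#' per year, treated as approximately one.
#'
#' @param pct_median median stratum percentage (e.g. 3.6 for 3.6%).
#' @param all_parrots_median median June--July total count.
#' @param fledge_rate young fledged per laying female per year.
#' @return expected recruits, rounded half-up to whole birds.
#' @examples
#' expected_recruits(3.6, 4571.5)  # 165 young
#' @export
expected_recruits <- function(pct_median, all_parrots_median,
                              fledge_rate = 1.0) {
  if (any(c(pct_median, all_parrots_median, fledge_rate) < 0, na.rm = TRUE))
    stop_roostdemog("expected_recruits() inputs must be non-negative",
                    "roostdemog_argument_error")
  round_half_up(pct_median / 100 * all_parrots_median * fledge_rate)
}

#' Post-fledging loss between two recruitment estimates
#'
#' The singleton-based estimate counts breeding attempts around fledging
#' time; the fledgling-based estimate counts young still in family flocks
#' months later. Their proportional shortfall, `1 - fledgling_based /
#' singleton_based`, is attributable to mortality (or dispersal) of the
#' fledged young in between, and is clamped to `[0, 1]` with a warning if
#' the fledgling-based estimate is the larger.
#'
#' @param singleton_based,fledgling_based expected recruits per year from
#'   [expected_recruits()] under the two strata.
#' @return fraction lost in `[0, 1]`; `NA` with a warning when
#'   `singleton_based` is zero.
#' @export
post_fledging_loss <- function(singleton_based, fledgling_based) {
  if (is.na(singleton_based) || singleton_based == 0) {
    warning("singleton-based estimate is zero; loss undefined", call. = FALSE)
    return(NA_real_)
  }
  loss <- 1 - fledgling_based / singleton_based
  if (loss < 0) {
    warning("fledgling-based estimate exceeds singleton-based; clamping loss to 0",
            call. = FALSE)
    loss <- 0
  }
  min(loss, 1)
}
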