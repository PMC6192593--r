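#' Published annual stratified summaries for the five Pantanal roosts
#'
#' The annual summary table published for the five-roost Blue-fronted
#' Amazon monitoring programme in the southern Pantanal (2004--2009), as
#' printed: per roost (and pooled over roosts) the June--July mean count
#' (`all_parrots`) and the August--September singleton, June--July paired
#' and June--July fledgling percentages, by year, with the printed median
#' and IQR columns. Values are the rounded printed numbers, shipped as a
#' reference input for the demographic estimators when the underlying
#' monthly count table is not at hand.
#'
#' @return data frame with columns `roost`, `stratum` (`all_parrots`,
#'   `singles_pct`, `paired_pct`, `fledglings_pct`), `y2004` ... `y2009`,
#'   `median`, `iqr`; missing roost-years are `NA`.
#' @examples
#' pub <- published_annual_summaries()
#' subset(pub, roost == "pooled" & stratum == "fledglings_pct")
#' @export
published_annual_summaries <- function() {
  path <- system.file("extdata", "annual_summary_published.csv",
                      package = "roostdemog", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(roost = "character"))
  out
}

#' Per-year values of one row of the published annual summary table
#'
#' @param roost roost label (`"1"` ... `"5"` or `"pooled"`).
#' @param stratum stratum name as in [published_annual_summaries()].
#' @return numeric vector of the non-missing yearly values.
#' @export
published_annual_values <- function(roost, stratum) {
  pub <- published_annual_summaries()
  row <- pub[pub$roost == roost & pub$stratum == stratum, ]
  if (nrow(row) != 1)
    stop_roostdemog("no published row for that roost and stratum",
                    "roostdemog_argument_error")
  v <- unlist(row[grep("^y[0-9]{4}$", names(row))])
  unname(v[!is.na(v)])
}
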