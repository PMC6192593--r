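## Orchestration: one entry point running validate / summarize / decompose /
## trends / permtest / demography / simulate end to end with deterministic,
## manifest-tracked artifacts. A thin command-line wrapper over this
## function ships in inst/scripts/roost-pipeline.R.

#' Read a synthetic-generator configuration from YAML or JSON
#'
#' The file may specify any subset of the [synthetic_config()] arguments
#' (`roosts` as a table, `levels`, `trends`, `templates`, `theta`, `phi`,
#' `young_probs`, `noise`); omitted entries keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("roosts", "levels", "trends", "templates", "theta", "phi",
             "young_probs", "noise")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop_roostdemog(paste0("unknown config key(s): ",
                           paste(bad, collapse = ", ")),
                    "roostdemog_config_error")
  if (!is.null(raw$roosts)) raw$roosts <- as.data.frame(raw$roosts)
  do.call(synthetic_config, raw)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the roost-count analysis pipeline
#'
#' One deterministic entry point over the package's modules. Subcommands:
#' \describe{
#'   \item{`validate`}{[validate_counts()] report.}
#'   \item{`summarize`}{annual [summary_table()] and monthly
#'     [monthly_median_table()].}
#'   \item{`decompose`}{[stl_decompose()] components and
#'     [range_standardize()]d seasonal profile for one roost x stratum.}
#'   \item{`trends`}{pooled total and fledgling [linear_trend()]s and the
#'     two family-flock [grouped_trend()]s.}
#'   \item{`permtest`}{seasonal permutation ANOVAs: pooled counts by
#'     month, and counts by roost x month.}
#'   \item{`demography`}{singleton- and fledgling-based recruitment and
#'     post-fledging loss from the annual summaries.}
#'   \item{`simulate`}{[generate_roost_counts()] to CSV.}
#'   \item{`all`}{everything above except `simulate`.}
#' }
#' Every subcommand draws its randomness from a child seed derived from
#' `seed` and the subcommand name, so artifacts are byte-stable for a
#' fixed configuration and partial reruns match the full run. A JSON
#' manifest lists each artifact with its MD5 hash alongside the seed and
#' permutation count used.
#'
#' @param command subcommand name (see above).
#' @param input path to a counts CSV (ignored by `simulate` when `config`
#'   is given), or a [roost_counts] table.
#' @param out_dir output directory, created if needed.
#' @param seed master seed.
#' @param n_perm permutations for all permutation tests.
#' @param fledge_rate young per laying female per year, for `demography`.
#' @param roost,stratum selection for `decompose` (defaults: pooled
#'   series, `all_parrots`).
#' @param trend_roosts roosts for the family-flock trend models; default
#'   all roosts.
#' @param config [synthetic_config()] or path to one, for `simulate`.
#' @return (invisibly) the manifest list; artifacts are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(command = c("all", "validate", "summarize",
                                     "decompose", "trends", "permtest",
                                     "demography", "simulate"),
                         input = NULL, out_dir = ".", seed = 1,
                         n_perm = 999, fledge_rate = 1.0,
                         roost = "pooled", stratum = "all_parrots",
                         trend_roosts = NULL, config = NULL) {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    artifacts <<- c(artifacts, path)
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    .write_json(x, path)
    artifacts <<- c(artifacts, path)
  }

  if (command == "simulate") {
    if (is.character(config)) config <- read_synthetic_config(config)
    config <- config %||% synthetic_config()
    tab <- generate_roost_counts(config,
                                 seed = child_seed(seed, "simulate"))
    emit_csv(tab, "synthetic_counts.csv")
  } else {
    if (is.null(input))
      stop_roostdemog("an input counts table is required",
                      "roostdemog_io_error")
    counts <- if (inherits(input, "roost_counts")) input
    else {
      if (!file.exists(input))
        stop_roostdemog(paste0("input file not found: ", input),
                        "roostdemog_io_error")
      read_counts(input)
    }
    pooled <- pool_roosts(counts)

    if (command %in% c("validate", "all"))
      emit_csv(validate_counts(counts), "validation_report.csv")

    if (command %in% c("summarize", "all")) {
      emit_csv(summary_table(counts), "annual_summary.csv")
      emit_csv(monthly_median_table(counts), "monthly_medians.csv")
    }

    if (command %in% c("decompose", "all")) {
      src <- if (identical(roost, "pooled")) pooled else counts
      dec <- stl_decompose(monthly_series(src, roost, stratum))
      emit_csv(dec$components,
               sprintf("decomposition_%s_%s.csv", roost, stratum))
      prof <- tryCatch(range_standardize(dec), error = function(e) NULL)
      if (!is.null(prof))
        emit_csv(data.frame(month = month.abb, profile = unname(prof)),
                 sprintf("seasonal_profile_%s_%s.csv", roost, stratum))
    }

    if (command %in% c("trends", "all")) {
      tr <- list(
        pooled_all_parrots = unclass(linear_trend(
          monthly_series(pooled, "pooled", "all_parrots"), permute = TRUE,
          n_perm = n_perm, seed = child_seed(seed, "trend_all"))),
        pooled_fledglings = unclass(linear_trend(
          monthly_series(pooled, "pooled", "fledglings"), permute = TRUE,
          n_perm = n_perm, seed = child_seed(seed, "trend_fledglings"))))
      for (resp in c("n_family_flocks", "mean_fledglings_per_flock")) {
        g <- tryCatch(
          grouped_trend(counts, resp, roosts = trend_roosts,
                        n_perm = n_perm,
                        seed = child_seed(seed, paste0("trend_", resp))),
          roostdemog_error = function(e) list(error = conditionMessage(e)))
        tr[[resp]] <- if (!is.null(g$error)) g
        else list(table = g$table, slopes = g$slopes, slope = g$slope,
                  slope_per_year = g$slope_per_year, n_obs = g$n_obs,
                  overall_mean = g$overall_mean,
                  r_squared = g$r_squared)
      }
      emit_json(tr, "trends.json")
    }

    if (command %in% c("permtest", "all")) {
      pooled_df <- as.data.frame(pooled)
      pooled_df$month <- factor(pooled_df$month, levels = 1:12)
      seasonal <- permutation_test(
        all_parrots ~ month, pooled_df, n_perm = n_perm,
        seed = child_seed(seed, "perm_month"))
      counts_df <- as.data.frame(counts)
      counts_df$month <- factor(counts_df$month, levels = 1:12)
      counts_df$roost <- factor(counts_df$roost)
      by_roost <- tryCatch(
        permutation_test(
          all_parrots ~ roost + month + roost:month, counts_df,
          n_perm = n_perm, seed = child_seed(seed, "perm_roost_month")),
        roostdemog_error = function(e) list(error = conditionMessage(e)))
      emit_json(list(pooled_by_month = unclass(seasonal),
                     by_roost_and_month = unclass(by_roost)),
                "permutation_tests.json")
    }

    if (command %in% c("demography", "all")) {
      st <- summary_table(counts)
      pick <- function(stat) st$median[st$roost == "pooled" &
                                         st$stratum == stat]
      total_med <- pick("all_parrots")
      singles_med <- pick("singles_pct")
      fledg_med <- pick("fledglings_pct")
      rec_s <- expected_recruits(singles_med, total_med, fledge_rate)
      rec_f <- expected_recruits(fledg_med, total_med, 1.0)
      emit_json(list(
        pooled_junjul_median = total_med,
        singles_pct_median = singles_med,
        fledglings_pct_median = fledg_med,
        breeding_attempt_proportion = breeding_attempt_proportion(singles_med),
        fledge_rate = fledge_rate,
        expected_recruits_singleton = rec_s,
        expected_recruits_fledgling = rec_f,
        post_fledging_loss = post_fledging_loss(rec_s, rec_f)),
        "demography.json")
    }
  }

  manifest <- list(
    command = command, seed = seed, n_perm = n_perm,
    artifacts = lapply(artifacts, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
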