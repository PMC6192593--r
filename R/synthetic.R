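## Stochastic generator of flock-size-stratified roost-count tables with
## the structure the analysis assumes: log-linear trends, 12-month seasonal
## templates, negative-binomial dispersion, an incubation-season singleton
## pulse, and per-flock fledgling draws.

.gen_strata <- c("singles", "pairs", "n_family_flocks", "large_flock_birds")

## Zero-sum 12-month template peaking June-July (attendance maximum).
## Values are pairwise distinct so the template's month rank order is
## well defined.
.tpl_junjul <- function(amp = 1) {
  s <- c(-0.2, -0.5, -0.62, -0.45, 0.02, 0.9, 0.8, -0.1, -0.3, 0.3,
         0.05, -0.4)
  amp * (s - mean(s))
}

## Zero-sum template peaking Nov-Feb (family flocks after fledging).
.tpl_postfledge <- function(amp = 1) {
  s <- c(0.62, 0.4, -0.2, -0.48, -0.62, -0.5, -0.32, -0.22, 0.02, 0.22,
         0.5, 0.58)
  amp * (s - mean(s))
}

#' Configuration for the synthetic roost-count generator
#'
#' Defines a small colony system shaped like a multi-year roost-monitoring
#' study: five roosts with staggered monitoring windows (61, 61, 61, 38 and
#' 28 months), per-roost log-level, per-month log-linear trend and zero-sum
#' 12-month seasonal template for each generated stratum, negative-binomial
#' dispersion, a breeding fraction `phi` that emits extra August--September
#' singletons in proportion to the roost's expected June--July total, and a
#' distribution of 1--4 fledged young per family flock. The defaults give
#' June--July attendance peaks, pair-dominated flock structure, a declining
#' family-flock stratum, a collapsing fifth roost, and no missing months
#' (matching a design in which every scheduled count was completed).
#'
#' @param roosts data frame with columns `roost`, `start_year`,
#'   `start_month`, `n_months`, `p_missing`.
#' @param levels named list per generated stratum (`singles`, `pairs`,
#'   `n_family_flocks`, `large_flock_birds`) of per-roost log-levels `a`.
#' @param trends named list per stratum of per-roost log-trends `b`
#'   (per month).
#' @param templates named list per stratum of 12-value zero-sum seasonal
#'   templates (shared across roosts).
#' @param theta negative-binomial dispersion (size); `Inf` gives Poisson.
#' @param phi breeding fraction in `[0, 1]`: expected August--September
#'   singleton excess as a share of the expected June--July total.
#' @param young_probs probabilities of 1, 2, 3 or 4 young per family
#'   flock.
#' @param noise `"nb"` (default), `"poisson"`, or `"none"` (deterministic
#'   expected values, for noise-free recovery checks).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(roosts = NULL, levels = NULL, trends = NULL,
                             templates = NULL, theta = 8, phi = 0.05,
                             young_probs = c(0.6, 0.3, 0.08, 0.02),
                             noise = c("nb", "poisson", "none")) {
  noise <- match.arg(noise)
  roosts <- roosts %||% data.frame(
    roost = as.character(1:5),
    start_year = c(2004, 2004, 2004, 2004, 2004),
    start_month = c(7, 7, 7, 7, 9),
    n_months = c(61, 61, 61, 38, 28),
    p_missing = 0)
  nr <- nrow(roosts)
  levels <- levels %||% list(
    singles = log(c(12, 8, 10, 8, 5)[seq_len(nr)]),
    pairs = log(c(250, 180, 150, 160, 80)[seq_len(nr)]),
    n_family_flocks = log(c(18, 12, 10, 14, 6)[seq_len(nr)]),
    large_flock_birds = log(c(350, 120, 100, 150, 40)[seq_len(nr)]))
  trends <- trends %||% list(
    singles = c(rep(0, nr - 1), -0.08),
    pairs = c(rep(0.003, nr - 1), -0.08),
    n_family_flocks = c(rep(-0.02, nr - 1), -0.08),
    large_flock_birds = c(rep(0, nr - 1), -0.08))
  templates <- templates %||% list(
    singles = rep(0, 12),
    pairs = .tpl_junjul(1),
    n_family_flocks = .tpl_postfledge(0.7),
    large_flock_birds = .tpl_junjul(0.8))
  templates <- lapply(templates, function(s) s - mean(s))
  cfg <- list(roosts = roosts, levels = levels, trends = trends,
              templates = templates, theta = theta, phi = phi,
              young_probs = young_probs / sum(young_probs), noise = noise)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  ok <- is.data.frame(cfg$roosts) &&
    all(c("roost", "start_year", "start_month", "n_months", "p_missing")
        %in% names(cfg$roosts)) &&
    all(cfg$roosts$p_missing >= 0 & cfg$roosts$p_missing <= 1) &&
    all(cfg$roosts$n_months >= 1)
  if (!ok)
    stop_roostdemog("invalid roosts table in synthetic config",
                    "roostdemog_argument_error")
  nr <- nrow(cfg$roosts)
  for (st in .gen_strata) {
    if (length(cfg$levels[[st]]) != nr || length(cfg$trends[[st]]) != nr)
      stop_roostdemog(paste0("levels/trends for '", st,
                             "' must have one value per roost"),
                      "roostdemog_argument_error")
    tpl <- cfg$templates[[st]]
    if (length(tpl) != 12 || abs(sum(tpl)) > 1e-8)
      stop_roostdemog(paste0("template for '", st,
                             "' must be 12 zero-sum values"),
                      "roostdemog_argument_error")
  }
  if (!(cfg$theta > 0))
    stop_roostdemog("theta must be positive (Inf for Poisson)",
                    "roostdemog_argument_error")
  if (cfg$phi < 0 || cfg$phi > 1)
    stop_roostdemog("phi must be in [0, 1]", "roostdemog_argument_error")
  if (length(cfg$young_probs) != 4 || any(cfg$young_probs < 0))
    stop_roostdemog("young_probs must be 4 non-negative probabilities",
                    "roostdemog_argument_error")
  invisible(cfg)
}

## Expected value of a generated stratum for roost index i at elapsed
## month t (0-based) and calendar month m.
.gen_mean <- function(cfg, st, i, t, m) {
  exp(cfg$levels[[st]][i] + cfg$trends[[st]][i] * t + cfg$templates[[st]][m])
}

## Expected June-July total bird count for roost i in the calendar year
## containing elapsed month t (months outside the monitoring window are
## still evaluated from the model).
.junjul_total_mean <- function(cfg, i, year) {
  r <- cfg$roosts[i, ]
  ts <- month_index(year, 6:7, r$start_year, r$start_month)
  mean(vapply(seq_along(ts), function(k) {
    t <- ts[k]; m <- c(6L, 7L)[k]
    mean_young <- sum(cfg$young_probs * (1:4))
    .gen_mean(cfg, "singles", i, t, m) +
      2 * .gen_mean(cfg, "pairs", i, t, m) +
      (2 + mean_young) * .gen_mean(cfg, "n_family_flocks", i, t, m) +
      .gen_mean(cfg, "large_flock_birds", i, t, m)
  }, numeric(1)))
}

.draw_count <- function(n, mu, cfg) {
  switch(cfg$noise,
         nb = if (is.infinite(cfg$theta)) stats::rpois(n, mu)
              else stats::rnbinom(n, mu = mu, size = cfg$theta),
         poisson = stats::rpois(n, mu),
         none = round_half_up(mu))
}

#' Generate a synthetic stratified roost-count table
#'
#' Draws, for every roost and monitored month, singleton, pair,
#' family-flock and large-flock counts from the generative model in
#' [synthetic_config()]: negative-binomial counts around log-linear
#' trend-plus-season means; an additional binomial singleton pulse in
#' August--September with success `phi` out of the roost's expected
#' June--July total; and per-flock fledgling numbers drawn independently
#' from the young distribution, so that `family_flock_birds = 2 *
#' n_family_flocks + fledglings` and the stratification identity holds by
#' construction. Months are then dropped independently with the roost's
#' missing-month probability.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the same seed always yields the same table.
#' @return a [roost_counts] table.
#' @examples
#' counts <- generate_roost_counts(synthetic_config(), seed = 1)
#' nrow(validate_counts(counts))  # 0: identities hold by construction
#' @export
generate_roost_counts <- function(config, seed = NULL) {
  validate_synthetic_config(config)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(config$roosts))) {
      r <- config$roosts[i, ]
      for (t in 0:(r$n_months - 1)) {
        cal <- month_shift(r$start_year, r$start_month, t)
        m <- cal$month
        singles <- .draw_count(1, .gen_mean(config, "singles", i, t, m),
                               config)
        if (m %in% c(8L, 9L) && config$phi > 0) {
          size <- round_half_up(.junjul_total_mean(config, i, cal$year))
          singles <- singles + if (config$noise == "none")
            round_half_up(config$phi * size)
          else stats::rbinom(1, size = size, prob = config$phi)
        }
        pairs <- .draw_count(1, .gen_mean(config, "pairs", i, t, m), config)
        nff <- .draw_count(1, .gen_mean(config, "n_family_flocks", i, t, m),
                           config)
        young <- if (nff == 0) 0
        else if (config$noise == "none") {
          mean_young <- sum(config$young_probs * (1:4))
          min(max(round_half_up(nff * mean_young), nff), 4 * nff)
        } else sum(sample(1:4, nff, replace = TRUE,
                          prob = config$young_probs))
        large <- .draw_count(1, .gen_mean(config, "large_flock_birds",
                                          i, t, m), config)
        ffb <- 2 * nff + young
        rows[[length(rows) + 1L]] <- data.frame(
          roost = r$roost, year = cal$year, month = m,
          all_parrots = singles + 2 * pairs + ffb + large,
          singles = singles, pairs = pairs, fledglings = young,
          family_flock_birds = ffb, large_flock_birds = large,
          keep = stats::runif(1) >= r$p_missing)
      }
    }
    tab <- do.call(rbind, rows)
    tab <- tab[tab$keep, setdiff(names(tab), "keep")]
    as_roost_counts(tab)
  })
}

#' Pipeline parameter-recovery experiment on synthetic roosts
#'
#' Generates `replicates` tables from one configuration and, for each, runs
#' the estimation pipeline: pooled family-flock (fledgling) trend slope
#' with a permutation p-value, seasonal-profile recovery for the pooled
#' pair counts, and the singleton-based breeding-fraction estimate.
#' Aggregates bias, RMSE, the trend-test rejection rate at `alpha`, and
#' the share of replicates recovering the trend's sign.
#'
#' @param config a [synthetic_config()].
#' @param replicates number of replicates (>= 10).
#' @param seed integer seed; replicate r uses child seed `seed + r`.
#' @param n_perm permutations for the trend test (default 199, enough for
#'   a 0.05-level decision).
#' @param alpha rejection level for the trend test.
#' @return list of class `recovery_report` with per-replicate `results`
#'   (data frame: `slope`, `p_trend`, `template_cor`, `phi_hat`) and
#'   aggregate `summary` (named vector).
#' @export
recovery_experiment <- function(config, replicates = 20, seed = 1,
                                n_perm = 199, alpha = 0.05) {
  if (replicates < 10)
    stop_roostdemog("recovery_experiment() needs at least 10 replicates",
                    "roostdemog_argument_error")
  validate_synthetic_config(config)
  res <- lapply(seq_len(replicates), function(rep) {
    tab <- generate_roost_counts(config, seed = seed + rep)
    pooled <- pool_roosts(tab)
    fl <- monthly_series(pooled, "pooled", "fledglings")
    tr <- linear_trend(fl, permute = TRUE, n_perm = n_perm,
                       seed = child_seed(seed + rep, "trend"))
    tcor <- tryCatch({
      dec <- stl_decompose(monthly_series(pooled, "pooled", "pairs"))
      stats::cor(dec$seasonal_months, config$templates$pairs,
                 method = "spearman")
    }, error = function(e) NA_real_)
    st <- summary_table(tab, pooled = TRUE)
    sp <- st$median[st$roost == "pooled" & st$stratum == "singles_pct"]
    data.frame(slope = tr$slope, p_trend = tr$p_perm,
               template_cor = tcor,
               phi_hat = breeding_attempt_proportion(sp))
  })
  results <- do.call(rbind, res)
  b <- config$trends$n_family_flocks[1]
  summary <- c(
    mean_slope = mean(results$slope),
    sign_recovery = mean(sign(results$slope) == sign(b)),
    rejection_rate = mean(results$p_trend <= alpha),
    mean_template_cor = mean(results$template_cor, na.rm = TRUE),
    phi_bias = mean(results$phi_hat) - config$phi,
    phi_rmse = sqrt(mean((results$phi_hat - config$phi)^2)))
  structure(list(results = results, summary = summary,
                 replicates = replicates, seed = seed, alpha = alpha),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Synthetic recovery experiment: %d replicates (seed %s)\n",
              x$replicates, format(x$seed)))
  print(round(x$summary, 4), ...)
  invisible(x)
}
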