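## Linear models with sequential (type-I) sums of squares and permutation
## p-values: ANOVA by raw response permutation, multi-term models by
## Freedman-Lane residual permutation, and ANCOVA with a parallelism check.

## Design matrix bookkeeping shared by the fitting and permutation paths.
## Returns the full-model QR, the term labels and the column blocks
## (by the model matrix 'assign' attribute, intercept excluded).
.design <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (!is.numeric(y))
    stop_roostdemog("response must be numeric", "roostdemog_design_error")
  for (v in names(mf)[-1])
    if (is.factor(mf[[v]]) && nlevels(droplevels(mf[[v]])) < 2)
      stop_roostdemog(paste0("factor '", v, "' has fewer than 2 observed levels"),
                      "roostdemog_design_error")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_roostdemog(paste0("rank-deficient design; aliased term(s): ",
                           paste(aliased, collapse = ", ")),
                    "roostdemog_design_error")
  }
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(mf), "term.labels")
  blocks <- lapply(seq_along(labels), function(j) which(asgn == j))
  list(mf = mf, y = y, X = X, qr = qrX, labels = labels, blocks = blocks,
       terms = attr(mf, "terms"))
}

## Sequential SS per term and residual SS for response y given a full-model
## QR whose columns are ordered intercept-first then term blocks. The
## squared entries of Q'y partition the regression SS by column.
.seq_ss <- function(qrX, blocks, y) {
  qty <- qr.qty(qrX, y)
  n <- length(y)
  p <- qrX$rank
  ss <- vapply(blocks, function(ix) sum(qty[ix]^2), numeric(1))
  sse <- if (p < n) sum(qty[(p + 1):n]^2) else 0
  list(ss = ss, sse = sse, df_res = n - p)
}

## F statistics from a sequential decomposition; saturated fits (residual
## MS 0) give F = 0 for terms with no SS and Inf otherwise.
.seq_F <- function(dec, df_t) {
  msr <- dec$sse / dec$df_res
  ifelse(rep(msr > 0, length(df_t)), (dec$ss / df_t) / msr,
         ifelse(dec$ss > 0, Inf, 0))
}

#' Fit a linear model with sequential sums of squares
#'
#' Ordinary least squares with treatment-coded factors. Each term is tested
#' in the declared order (type-I decomposition), so, e.g., in
#' `count ~ roost + month + roost:month` the month effect is assessed after
#' removing roost differences.
#'
#' @param formula model formula.
#' @param data data frame with the model variables; rows with missing
#'   values in the used variables are dropped.
#' @return list of class `lm_terms` with `table` (data frame: `term`,
#'   `df`, `ss`, `F`, `p_classical`), `df_residual`, `r_squared`, `n_obs`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' fit_linear_model(y ~ g, d)  # F = 13.5 on (1, 4) df
#' @export
fit_linear_model <- function(formula, data) {
  des <- .design(formula, data)
  dec <- .seq_ss(des$qr, des$blocks, des$y)
  df_t <- lengths(des$blocks)
  Fstat <- .seq_F(dec, df_t)
  sst <- sum((des$y - mean(des$y))^2)
  out <- list(
    table = data.frame(term = des$labels, df = df_t, ss = dec$ss, F = Fstat,
                       p_classical = stats::pf(Fstat, df_t, dec$df_res,
                                               lower.tail = FALSE),
                       stringsAsFactors = FALSE),
    df_residual = dec$df_res,
    r_squared = if (sst > 0) 1 - dec$sse / sst else 0,
    n_obs = length(des$y))
  ## constant response: no variance to attribute
  if (sst == 0) out$table$F[] <- 0
  class(out) <- "lm_terms"
  out
}

#' Permutation test for every term of a linear model
#'
#' Attaches resampling p-values to the sequential F statistics of
#' [fit_linear_model()]. Single-term models permute the raw response;
#' models with nuisance terms use Freedman-Lane permutation, in which each
#' term's null is built by permuting the residuals of the model containing
#' all *other* terms and re-fitting the full model. `p = (1 + #permuted F
#' >= observed F) / (n_perm + 1)`, so p can never be smaller than
#' `1/(n_perm + 1)`; ties count against the hypothesis.
#'
#' @param formula model formula.
#' @param data data frame with the model variables.
#' @param n_perm number of permutations (>= 99; default 4999).
#' @param seed integer seed; set for reproducible p-values.
#' @param scheme `"auto"` (raw for one term, Freedman-Lane otherwise),
#'   `"raw"`, or `"freedman-lane"`.
#' @return object of class `permutation_result`: `table` (data frame
#'   `term`, `df`, `F`, `p_perm`, `p_classical`), `df_residual`,
#'   `r_squared`, `n_obs`, `n_perm`, `seed`, `scheme`.
#' @export
permutation_test <- function(formula, data, n_perm = 4999, seed = NULL,
                             scheme = c("auto", "raw", "freedman-lane")) {
  scheme <- match.arg(scheme)
  if (n_perm < 99)
    stop_roostdemog("n_perm must be at least 99", "roostdemog_argument_error")
  fit <- fit_linear_model(formula, data)
  des <- .design(formula, data)
  n <- length(des$y)
  k <- length(des$labels)
  if (scheme == "auto") scheme <- if (k == 1) "raw" else "freedman-lane"
  tol <- 1e-8 * pmax(1, abs(fit$table$F))

  count <- numeric(k)
  if (scheme == "raw") {
    with_seed(seed, for (b in seq_len(n_perm)) {
      dec <- .seq_ss(des$qr, des$blocks, des$y[sample.int(n)])
      Fb <- .seq_F(dec, lengths(des$blocks))
      count <- count + (Fb >= fit$table$F - tol)
    })
  } else {
    ## reduced model per term: all other terms (plus intercept)
    reduced <- lapply(seq_len(k), function(j) {
      Xr <- des$X[, c(1L, unlist(des$blocks[-j])), drop = FALSE]
      qrR <- qr(Xr)
      list(fitted = qr.fitted(qrR, des$y), resid = qr.resid(qrR, des$y))
    })
    with_seed(seed, for (b in seq_len(n_perm)) {
      prm <- sample.int(n)
      for (j in seq_len(k)) {
        ystar <- reduced[[j]]$fitted + reduced[[j]]$resid[prm]
        dec <- .seq_ss(des$qr, des$blocks, ystar)
        Fb <- .seq_F(dec, lengths(des$blocks))[j]
        count[j] <- count[j] + (Fb >= fit$table$F[j] - tol[j])
      }
    })
  }
  tab <- fit$table[, c("term", "df", "F")]
  tab$p_perm <- (1 + count) / (n_perm + 1)
  tab$p_classical <- fit$table$p_classical
  structure(list(table = tab, df_residual = fit$df_residual,
                 r_squared = fit$r_squared, n_obs = fit$n_obs,
                 n_perm = n_perm, seed = seed, scheme = scheme),
            class = "permutation_result")
}

#' Permutation ANCOVA with a parallel-slopes check
#'
#' Fits the model including the covariate-by-factor interaction first. If
#' the interaction is non-significant at `alpha` it is dropped and the
#' additive (common-slope) ANCOVA is returned, flagged `"parallel-slopes"`;
#' otherwise the interaction model itself is returned, flagged
#' `"non-parallel"`, since a common slope would then be meaningless.
#'
#' @param formula model with exactly one covariate-by-factor interaction,
#'   e.g. `y ~ roost + time + roost:time` (or `y ~ roost * time`).
#' @param data data frame with the model variables.
#' @param alpha significance threshold for the interaction (default 0.05).
#' @inheritParams permutation_test
#' @return a [permutation_test()] result with extra fields `slopes`
#'   (`"parallel-slopes"` or `"non-parallel"`) and `interaction`
#'   (the interaction term's row from the full-model fit).
#' @export
ancova_with_parallelism <- function(formula, data, alpha = 0.05,
                                    n_perm = 4999, seed = NULL) {
  full <- permutation_test(formula, data, n_perm = n_perm, seed = seed,
                           scheme = "freedman-lane")
  inter <- grepl(":", full$table$term, fixed = TRUE)
  if (sum(inter) != 1)
    stop_roostdemog("formula must contain exactly one interaction term",
                    "roostdemog_design_error")
  int_row <- full$table[inter, ]
  if (int_row$p_perm >= alpha) {
    labs <- full$table$term[!inter]
    reduced_formula <- stats::reformulate(labs, response = formula[[2]])
    res <- permutation_test(reduced_formula, data, n_perm = n_perm,
                            seed = seed, scheme = "freedman-lane")
    res$slopes <- "parallel-slopes"
  } else {
    res <- full
    res$slopes <- "non-parallel"
  }
  res$interaction <- int_row
  res
}

#' @export
print.lm_terms <- function(x, ...) {
  cat(sprintf("Linear model (sequential SS): n = %d, residual df = %d, r2 = %.3f\n",
              x$n_obs, x$df_residual, x$r_squared))
  print(x$table, row.names = FALSE, ...)
  invisible(x)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation %s: n = %d, residual df = %d, r2 = %.3f, %d permutations%s\n",
    x$scheme, x$n_obs, x$df_residual, x$r_squared, x$n_perm,
    if (is.null(x$seed)) "" else sprintf(" (seed %s)", format(x$seed))))
  tab <- x$table
  floorp <- 1 / (x$n_perm + 1)
  tab$p_perm <- ifelse(tab$p_perm <= floorp,
                       sprintf("< %.4g", floorp),
                       sprintf("%.4g", tab$p_perm))
  print(tab, row.names = FALSE, ...)
  if (!is.null(x$slopes)) cat("slopes:", x$slopes, "\n")
  invisible(x)
}
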