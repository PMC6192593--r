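## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used when converting continuous
#' estimates to whole birds: 164.5 rounds to 165, not 164.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 164.574))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## 0-based month index of (year, month) relative to an origin (year0, month0).
month_index <- function(year, month, year0, month0) {
  (year - year0) * 12L + (month - month0)
}

## Inverse of month_index: origin plus k calendar months.
month_shift <- function(year0, month0, k) {
  m0 <- (month0 - 1L) + k
  list(year = year0 + m0 %/% 12L, month = m0 %% 12L + 1L)
}

## set.seed() scoped to the calling expression; restores prior RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a child seed below 2^31 from a parent seed and a stream label.
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.double(seed) * 7919 + offs) %% 2147483647
}

stop_roostdemog <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "roostdemog_error")))
}
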