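# Independent oracle implementations used to cross-check package code.
# These deliberately use different algorithms (explicit sums, normal
# equations, enumeration) from the implementation paths they verify.

# All n! permutations of 1:n as a matrix (rows), by recursive insertion.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

# Sample quantile by explicit sort + plotting position h = (n - 1) p.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}

# One-point tricube-weighted polynomial fit by explicit normal equations.
oracle_loess_point <- function(t, y, t0, span, degree) {
  n <- length(t)
  q <- min(n, max(ceiling(span * n), degree + 2))
  d <- abs(t - t0)
  keep <- order(d)[seq_len(q)]
  dmax <- d[keep[q]]
  w <- if (dmax == 0) rep(1, q) else (1 - pmin(d[keep] / dmax, 1)^3)^3
  X <- outer(t[keep] - t0, 0:degree, `^`)
  W <- diag(w, q)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[keep])
  beta[1]
}

# One-factor ANOVA F from explicit between/within sums of squares.
oracle_anova_F <- function(y, g) {
  g <- as.factor(g)
  gm <- tapply(y, g, mean)
  nn <- tapply(y, g, length)
  ssb <- sum(nn * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  k <- nlevels(g)
  (ssb / (k - 1)) / (ssw / (length(y) - k))
}

# A small clean canonical count table used across tests.
toy_counts <- function() {
  as_roost_counts(data.frame(
    roost = rep(c("A", "B"), each = 4),
    year = 2005,
    month = rep(6:9, 2),
    all_parrots = c(300, 300, 120, 110, 400, 400, 150, 160),
    singles = c(4, 2, 10, 14, 6, 4, 20, 24),
    pairs = c(90, 110, 30, 20, 120, 130, 40, 40),
    fledglings = c(12, 8, 6, 8, 10, 12, 6, 8),
    family_flock_birds = c(28, 20, 14, 18, 26, 28, 14, 16),
    large_flock_birds = c(88, 58, 36, 38, 128, 108, 36, 40)))
}
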