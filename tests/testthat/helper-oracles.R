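# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (qbeta for the interval, the closed-form n):
# the interval oracle bisects the binomial tail sums directly, and the
# power oracle evaluates the asymptotic normal power expression.

# Clopper-Pearson bounds by bisection on pbinom tail sums.
cp_oracle <- function(x, n, level = 0.95, tol = 1e-12) {
  a <- (1 - level) / 2
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    # P(X >= x | n, p) grows with p; find p where it crosses a
    bisect(function(p) (1 - pbinom(x - 1, n, p)) - a, 0, 1)
  upper <- if (x == n) 1 else
    # P(X <= x | n, p) falls with p; sign flip makes the crossing increasing
    bisect(function(p) a - pbinom(x, n, p), 0, 1)
  c(lower = lower, upper = upper)
}

# Exhaustive scan for the smallest n whose rounded expected success count
# yields a CP lower bound at or above the floor (all quantities in percent).
min_n_oracle <- function(point_pct, floor_pct, level = 0.95, n_max = 500) {
  for (n in seq_len(n_max)) {
    x <- min(floor(point_pct / 100 * n + 0.5), n)
    b <- cp_oracle(x, n, level)
    if (b["lower"] >= floor_pct / 100) return(n)
  }
  NA_integer_
}

# Expected-count 2x2 table on a large population: predictive values by
# direct division of expected cell counts.
adjusted_pv_oracle <- function(se, sp, prev, N = 1e7) {
  tp <- se * prev * N
  fn <- (1 - se) * prev * N
  tn <- sp * (1 - prev) * N
  fp <- (1 - sp) * (1 - prev) * N
  c(ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

# Asymptotic power of the unpooled two-sample z-test at per-group size n.
asymptotic_power <- function(pc, pn, n, alpha, margin = NULL) {
  se <- sqrt((pc * (1 - pc) + pn * (1 - pn)) / n)
  if (is.null(margin)) {
    z <- qnorm(1 - alpha / 2)
    pnorm((pn - pc) / se - z) + pnorm(-(pn - pc) / se - z)
  } else {
    pnorm((pn - pc + margin) / se - qnorm(1 - alpha))
  }
}
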