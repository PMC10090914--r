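#' Monte Carlo verification of a computed sample size
#'
#' Draws repeated pairs of binomial samples at assumed true proportions and
#' applies the design's decision rule, giving the empirical power (or, when
#' simulated under the null, the empirical type I error) of the design at a
#' given per-group size. The decision rule matches the sizing formula's
#' variance structure — an unpooled-variance z-test, not an exact test — so
#' that the simulation verifies exactly the approximation the size was
#' computed from:
#'
#' * superiority: reject when \eqn{|z| > z_{1-\alpha/2}} for
#'   \eqn{z = (\hat p_n - \hat p_c)/\sqrt{\hat v}}, two-sided;
#' * non-inferiority: reject (declare non-inferior) when
#'   \eqn{(\hat p_n - \hat p_c + d)/\sqrt{\hat v} > z_{1-\alpha}}, one-sided;
#'
#' with \eqn{\hat v = [\hat p_c(1-\hat p_c) + \hat p_n(1-\hat p_n)]/n}. When
#' both arms are degenerate (all successes or all failures) the estimated
#' variance is floored at a small epsilon so the statistic is defined: a
#' zero observed difference then never rejects under superiority, while
#' under non-inferiority the positive margin forces rejection (the data are
#' perfectly consistent with "not worse").
#'
#' @param design A `"samplesize_result"` (from [size_superiority] or
#'   [size_noninferiority]) supplying the hypothesis, alpha and margin.
#' @param n_per_group Patients per group to simulate (>= 2); defaults to the
#'   design's computed `n_per_group`.
#' @param true_p_control,true_p_new True success proportions to simulate
#'   under; defaults to the design's assumed proportions.
#' @param reps Number of Monte Carlo replicates (>= 1000).
#' @param seed Integer seed; identical `(seed, reps, design)` give identical
#'   results.
#' @return An object of class `"power_sim_result"`: a list with `reps`,
#'   `seed`, `rejections`, `empirical_power` (= rejections/reps) and `mc_se`
#'   (binomial standard error of the estimate), plus the simulated truth.
#' @examples
#' d <- size_superiority(0.80, 0.90)
#' simulate_power(d, reps = 5000, seed = 1)
#' @export
simulate_power <- function(design, n_per_group = design$n_per_group,
                           true_p_control = design$p_control,
                           true_p_new = design$p_new,
                           reps = 10000, seed = 1L) {
  if (!inherits(design, "samplesize_result")) {
    stop("`design` must be a samplesize_result", call. = FALSE)
  }
  if (reps < 1000) stop("`reps` must be at least 1000", call. = FALSE)
  if (n_per_group < 2) stop("`n_per_group` must be at least 2", call. = FALSE)
  check_probability(true_p_control, "true_p_control")
  check_probability(true_p_new, "true_p_new")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  xc <- stats::rbinom(reps, n_per_group, true_p_control)
  xn <- stats::rbinom(reps, n_per_group, true_p_new)
  pc_hat <- xc / n_per_group
  pn_hat <- xn / n_per_group
  # epsilon floor keeps z defined when both arms are degenerate
  v <- pmax(pc_hat * (1 - pc_hat) + pn_hat * (1 - pn_hat), 1e-12) /
    n_per_group
  if (design$hypothesis == "superiority") {
    z <- (pn_hat - pc_hat) / sqrt(v)
    reject <- abs(z) > stats::qnorm(1 - design$alpha / 2)
  } else {
    z <- (pn_hat - pc_hat + design$margin) / sqrt(v)
    reject <- z > stats::qnorm(1 - design$alpha)
  }
  k <- sum(reject)
  emp <- k / reps
  structure(
    list(hypothesis = design$hypothesis,
         n_per_group = as.integer(n_per_group),
         true_p_control = true_p_control, true_p_new = true_p_new,
         alpha = design$alpha, margin = design$margin,
         reps = as.integer(reps), seed = as.integer(seed),
         rejections = k, empirical_power = emp,
         mc_se = sqrt(emp * (1 - emp) / reps)),
    class = "power_sim_result"
  )
}

#' @export
print.power_sim_result <- function(x, ...) {
  cat(sprintf("Monte Carlo check (%s, %d reps, seed %d)\n",
              x$hypothesis, x$reps, x$seed))
  cat(sprintf("  simulated truth: control %.4g, new %.4g, n/group %d\n",
              x$true_p_control, x$true_p_new, x$n_per_group))
  cat(sprintf("  rejection rate: %.4f (MC se %.4f)\n",
              x$empirical_power, x$mc_se))
  invisible(x)
}

#' Empirical power across a grid of sample sizes
#'
#' Runs [simulate_power] at each size in `n_grid`, each with a deterministic
#' sub-seed derived from `seed` and the size itself (so the result for a
#' given n does not depend on the grid's order or contents).
#'
#' @inheritParams simulate_power
#' @param n_grid Non-empty ascending vector of per-group sizes.
#' @return A data.frame with columns `n`, `empirical_power`, `mc_se`.
#' @examples
#' d <- size_noninferiority(0.80, 0.80, margin = 0.05)
#' power_curve(d, c(500, 1097, 2000), reps = 2000, seed = 7)
#' @export
power_curve <- function(design, n_grid, reps = 10000, seed = 1L,
                        true_p_control = design$p_control,
                        true_p_new = design$p_new) {
  if (length(n_grid) == 0) stop("`n_grid` must be non-empty", call. = FALSE)
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop("`n_grid` must be strictly ascending", call. = FALSE)
  }
  rows <- lapply(n_grid, function(n) {
    r <- simulate_power(design, n_per_group = n,
                        true_p_control = true_p_control,
                        true_p_new = true_p_new,
                        reps = reps, seed = subseed_for(seed, n))
    data.frame(n = n, empirical_power = r$empirical_power, mc_se = r$mc_se)
  })
  do.call(rbind, rows)
}

# Deterministic sub-seed from (master seed, n); kept below 2^31 - 1.
subseed_for <- function(seed, n) {
  as.integer((as.double(seed) * 40503 + as.double(n) * 69069) %% 2147483647)
}
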