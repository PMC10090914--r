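#' Exact Clopper-Pearson confidence interval for a binomial proportion
#'
#' Computes the two-sided exact (Clopper-Pearson) confidence interval for a
#' proportion observed as `successes` out of `trials`. The interval inverts
#' the binomial tail probabilities: the lower bound solves
#' \eqn{P(X \ge x \mid n, p) = \alpha/2} and the upper bound solves
#' \eqn{P(X \le x \mid n, p) = \alpha/2}, with \eqn{\alpha = 1 - level}.
#' The bounds are evaluated through the beta-quantile characterization
#' (`qbeta`), which is exact for this inversion. When `successes = 0` the
#' lower bound is exactly 0; when `successes = trials` the upper bound is
#' exactly 1.
#'
#' @param successes Number of successes (non-negative integer).
#' @param trials Number of trials (positive integer).
#' @param level Confidence level in (0, 1); typically 0.95 or 0.99.
#'
#' @return An object of class `"cp_ci"`: a list with elements `successes`,
#'   `trials`, `estimate` (the point estimate successes/trials), `level`,
#'   `lower` and `upper` (both on the proportion scale in \[0, 1\]).
#'
#' @examples
#' clopper_pearson_ci(143, 150)        # (0.906, 0.981)
#' clopper_pearson_ci(0, 20)$lower     # exactly 0
#' @export
clopper_pearson_ci <- function(successes, trials, level = 0.95) {
  if (length(trials) != 1L || !is.finite(trials) || trials < 1 ||
      trials != round(trials)) {
    stop("`trials` must be a single positive integer", call. = FALSE)
  }
  if (length(successes) != 1L || !is.finite(successes) || successes < 0 ||
      successes > trials || successes != round(successes)) {
    stop("`successes` must be an integer in [0, trials]", call. = FALSE)
  }
  check_probability(level, "level", open = TRUE)
  x <- as.integer(round(successes))
  n <- as.integer(round(trials))
  alpha <- 1 - level
  lower <- if (x == 0L) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  structure(
    list(successes = x, trials = n, estimate = x / n,
         level = level, lower = lower, upper = upper),
    class = "cp_ci"
  )
}

#' @export
print.cp_ci <- function(x, digits = 4, ...) {
  cat(sprintf("Exact (Clopper-Pearson) %g%% confidence interval\n",
              100 * x$level))
  cat(sprintf("  observed : %d / %d  (%.*f)\n",
              x$successes, x$trials, digits, x$estimate))
  cat(sprintf("  interval : (%.*f, %.*f)\n",
              digits, x$lower, digits, x$upper))
  cat(sprintf("  percent  : (%.1f%%, %.1f%%)\n",
              100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Midpoint point estimate for confidence-bound sizing
#'
#' For a target lower confidence bound expressed in percent, returns the
#' midpoint of the interval between the target and 100%. This is the working
#' assumption used when sizing a non-comparative validation study: if the
#' lower CI bound must reach, say, 90%, the metric's point estimate is taken
#' as 95%, the middle of 90-100%. For small samples this assumption is a
#' heuristic, not a guarantee.
#'
#' @param target_lower Target lower confidence bound, in percent (0-100).
#' @return The assumed point estimate, in percent.
#' @examples
#' midpoint_estimate(90)  # 95
#' midpoint_estimate(80)  # 90
#' @export
midpoint_estimate <- function(target_lower) {
  if (length(target_lower) != 1L || !is.finite(target_lower) ||
      target_lower < 0 || target_lower > 100) {
    stop("`target_lower` must be a percentage in [0, 100]", call. = FALSE)
  }
  (target_lower + 100) / 2
}

#' Smallest sample size achieving a target lower confidence bound
#'
#' Solves the inverse confidence-interval problem: finds the smallest number
#' of trials `n` such that the exact Clopper-Pearson interval for the
#' expected number of successes (`round_half_up(point_estimate * n / 100)`)
#' has a lower bound at least `target_lower`. The expected success count is
#' rounded half-up (142.5 -> 143), the convention that reproduces published
#' worked values for this sizing procedure.
#'
#' @param point_estimate Assumed point estimate of the metric, in percent.
#' @param target_lower Required lower confidence bound, in percent; must be
#'   strictly below `point_estimate`.
#' @param level Confidence level in (0, 1).
#' @param n_max Upper end of the search range (default 100000). The search
#'   fails loudly if no `n` up to `n_max` satisfies the bound, which happens
#'   when `target_lower` is very close to `point_estimate`.
#'
#' @return An object of class `"min_n_result"`: a list with `n` (the minimal
#'   sample size), `successes` (the rounded expected count at `n`), `ci` (the
#'   achieved `cp_ci` at `n`), and the echoed inputs.
#' @examples
#' min_n_for_lower_bound(95, 90)   # smallest n with 95% CI lower bound >= 90%
#' @export
min_n_for_lower_bound <- function(point_estimate, target_lower,
                                  level = 0.95, n_max = 100000L) {
  for (nm in c("point_estimate", "target_lower")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 100) {
      stop(sprintf("`%s` must be a percentage in [0, 100]", nm),
           call. = FALSE)
    }
  }
  check_probability(level, "level", open = TRUE)
  if (point_estimate <= target_lower) {
    stop("`point_estimate` must exceed `target_lower`: the lower confidence ",
         "bound can never reach the point estimate at any finite n",
         call. = FALSE)
  }
  p <- point_estimate / 100
  floor_ <- target_lower / 100
  best_lower <- -Inf
  for (n in seq_len(n_max)) {
    x <- round_half_up(p * n)
    if (x > n) x <- n
    ci <- clopper_pearson_ci(x, n, level)
    if (ci$lower >= floor_) {
      return(structure(
        list(n = n, successes = x, ci = ci,
             point_estimate = point_estimate, target_lower = target_lower,
             level = level),
        class = "min_n_result"
      ))
    }
    if (ci$lower > best_lower) best_lower <- ci$lower
  }
  stop(sprintf(
    paste0("no n <= %d achieves lower bound %.4g%%; best achieved lower ",
           "bound was %.4g%%"),
    n_max, target_lower, 100 * best_lower), call. = FALSE)
}

#' @export
print.min_n_result <- function(x, ...) {
  cat(sprintf(
    "Minimal n for lower %g%% confidence bound >= %g%% at point estimate %g%%\n",
    100 * x$level, x$target_lower, x$point_estimate))
  cat(sprintf("  n = %d (expected successes %d)\n", x$n, x$successes))
  cat(sprintf("  achieved interval: (%.1f%%, %.1f%%)\n",
              100 * x$ci$lower, 100 * x$ci$upper))
  invisible(x)
}

# Round half away from zero at .5 (142.5 -> 143), unlike base round()'s
# banker's rounding; sizing conventions require half-up.
round_half_up <- function(x) {
  floor(x + 0.5)
}

check_probability <- function(x, name, open = FALSE) {
  ok <- length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must be a probability in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(TRUE)
}
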