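#' Sample size for comparing two binary proportions
#'
#' Per-group sample sizes for the two hypotheses that arise when a new
#' diagnostic test or a model-guided treatment strategy is compared with an
#' existing one on a binary endpoint (accuracy, or success rate in a
#' two-arm trial):
#'
#' * **Superiority** — the new test/strategy is better by a clinically
#'   meaningful amount. Tested two-sided at level `alpha`:
#'   \deqn{n = \left\lceil \frac{(z_{1-\alpha/2} + z_{power})^2\,
#'     [p_c(1-p_c) + p_n(1-p_n)]}{(p_n - p_c)^2} \right\rceil}
#' * **Non-inferiority** — the new test/strategy is at most a margin `d`
#'   worse. Tested one-sided at level `alpha`:
#'   \deqn{n = \left\lceil \frac{(z_{1-\alpha} + z_{power})^2\,
#'     [p_c(1-p_c) + p_n(1-p_n)]}{(p_n - p_c + d)^2} \right\rceil}
#'
#' Both use the unpooled normal approximation with full-precision normal
#' quantiles and no continuity correction, and round up. The `framing`
#' distinguishes a cross-sectional diagnostic comparison, where every test
#' is applied to the same patients so the study needs one sample of
#' `n_per_group` patients, from a two-arm randomized trial, where the total
#' is `2 * n_per_group`. (The unpaired formula is used in both framings; no
#' paired-data correction is applied.)
#'
#' Proportions may be given in either orientation: `rates = "success"`
#' (accuracy / success rate, the scale the formula works on) or
#' `rates = "event"` (disease/failure frequency), in which case each p is
#' replaced by 1 - p before sizing. Only 1:1 allocation is supported;
#' unequal ratios are rejected.
#'
#' @param p_control Accuracy of the old test, or control-arm rate.
#' @param p_new Accuracy of the new test, or experimental-arm rate.
#' @param alpha Type I error probability (default 0.05). Interpreted
#'   two-sided for superiority, one-sided for non-inferiority.
#' @param power Desired statistical power (default 0.90; 0.80 is the
#'   accepted minimum).
#' @param margin Non-inferiority margin d > 0: the largest clinically
#'   acceptable deficit of the new test.
#' @param framing `"paired-diagnostic"` (one patient sample, all tests
#'   applied to each patient) or `"two-arm-rct"` (two parallel groups).
#' @param rates Orientation of `p_control` / `p_new`: `"success"` or
#'   `"event"`.
#' @param inflate_pct Optional dropout inflation percentage (0-50) applied
#'   to the total.
#' @param ratio Allocation ratio between groups; only 1 (equal allocation)
#'   is supported, any other value is rejected.
#'
#' @return An object of class `"samplesize_result"`: a list with
#'   `n_per_group`, `n_total` (equal to `n_per_group` in the
#'   paired-diagnostic framing, twice it in the two-arm framing),
#'   `n_inflated` (or `NA`), `n_unrounded`, the z-quantiles and variance
#'   term used, and the echoed design.
#' @examples
#' size_superiority(0.80, 0.90)                       # 263 per group
#' size_noninferiority(0.80, 0.80, margin = 0.05)     # 1097 per group
#' size_noninferiority(0.80, 0.82, margin = 0.05)     # 538 per group
#' @export
size_superiority <- function(p_control, p_new, alpha = 0.05, power = 0.90,
                             framing = c("paired-diagnostic", "two-arm-rct"),
                             rates = c("success", "event"),
                             inflate_pct = NULL, ratio = 1) {
  framing <- match.arg(framing)
  rates <- match.arg(rates)
  check_equal_allocation(ratio)
  p <- normalize_rates(p_control, p_new, rates)
  check_probability(alpha, "alpha", open = TRUE)
  check_probability(power, "power", open = TRUE)
  if (p$control == p$new) {
    stop("superiority requires p_new != p_control: no finite sample size ",
         "can detect a zero difference", call. = FALSE)
  }
  z_alpha <- stats::qnorm(1 - alpha / 2)
  z_power <- stats::qnorm(power)
  variance <- p$control * (1 - p$control) + p$new * (1 - p$new)
  n_raw <- (z_alpha + z_power)^2 * variance / (p$new - p$control)^2
  build_samplesize_result(
    hypothesis = "superiority", p_control = p$control, p_new = p$new,
    alpha = alpha, power = power, margin = NA_real_, framing = framing,
    z_alpha = z_alpha, z_power = z_power, variance = variance,
    n_raw = n_raw, inflate_pct = inflate_pct)
}

#' @rdname size_superiority
#' @export
size_noninferiority <- function(p_control, p_new, margin,
                                alpha = 0.05, power = 0.90,
                                framing = c("paired-diagnostic", "two-arm-rct"),
                                rates = c("success", "event"),
                                inflate_pct = NULL, ratio = 1) {
  framing <- match.arg(framing)
  rates <- match.arg(rates)
  check_equal_allocation(ratio)
  p <- normalize_rates(p_control, p_new, rates)
  check_probability(alpha, "alpha", open = TRUE)
  check_probability(power, "power", open = TRUE)
  if (length(margin) != 1L || !is.finite(margin) || margin <= 0 ||
      margin >= 1) {
    stop("`margin` must be a proportion in (0, 1)", call. = FALSE)
  }
  if (p$new - p$control + margin <= 0) {
    stop("p_new - p_control + margin must be positive: the new test is ",
         "assumed worse by at least the margin, so non-inferiority cannot ",
         "be shown at any sample size", call. = FALSE)
  }
  z_alpha <- stats::qnorm(1 - alpha)
  z_power <- stats::qnorm(power)
  variance <- p$control * (1 - p$control) + p$new * (1 - p$new)
  n_raw <- (z_alpha + z_power)^2 * variance /
    (p$new - p$control + margin)^2
  build_samplesize_result(
    hypothesis = "noninferiority", p_control = p$control, p_new = p$new,
    alpha = alpha, power = power, margin = margin, framing = framing,
    z_alpha = z_alpha, z_power = z_power, variance = variance,
    n_raw = n_raw, inflate_pct = inflate_pct)
}

check_equal_allocation <- function(ratio) {
  if (length(ratio) != 1L || !is.finite(ratio) || ratio != 1) {
    stop("unequal allocation ratios (e.g. 3:1) are outside the scope of ",
         "this sizing formula; only ratio = 1 is supported", call. = FALSE)
  }
  invisible(TRUE)
}

normalize_rates <- function(p_control, p_new, rates) {
  check_probability(p_control, "p_control", open = TRUE)
  check_probability(p_new, "p_new", open = TRUE)
  if (rates == "event") {
    list(control = 1 - p_control, new = 1 - p_new)
  } else {
    list(control = p_control, new = p_new)
  }
}

build_samplesize_result <- function(hypothesis, p_control, p_new, alpha,
                                    power, margin, framing, z_alpha, z_power,
                                    variance, n_raw, inflate_pct) {
  n_per_group <- as.integer(ceiling(n_raw))
  n_total <- if (framing == "two-arm-rct") 2L * n_per_group else n_per_group
  res <- structure(
    list(hypothesis = hypothesis,
         p_control = p_control, p_new = p_new,
         alpha = alpha, power = power, margin = margin,
         framing = framing,
         z_alpha = z_alpha, z_power = z_power, variance = variance,
         n_unrounded = n_raw,
         n_per_group = n_per_group, n_total = n_total,
         n_inflated = NA_integer_, inflate_pct = NA_real_),
    class = "samplesize_result"
  )
  if (!is.null(inflate_pct)) res <- inflate_for_dropout(res, inflate_pct)
  res
}

#' Inflate a computed sample size for expected dropout
#'
#' Planned totals should be increased by 5-10% to stay powered under
#' dropouts and protocol deviations, especially when power was set at the
#' minimum 0.80. The inflated total is `ceiling(n_total * (1 + pct/100))`.
#'
#' @param result A `"samplesize_result"` from [size_superiority] or
#'   [size_noninferiority].
#' @param pct Inflation percentage, between 0 and 50.
#' @return The same object with `n_inflated` and `inflate_pct` filled in.
#' @examples
#' inflate_for_dropout(size_superiority(0.80, 0.90), 10)  # total 263 -> 290
#' @export
inflate_for_dropout <- function(result, pct) {
  if (!inherits(result, "samplesize_result")) {
    stop("`result` must be a samplesize_result", call. = FALSE)
  }
  result$n_inflated <- inflate_total(result$n_total, pct)
  result$inflate_pct <- pct
  result
}

inflate_total <- function(n_total, pct) {
  if (length(pct) != 1L || !is.finite(pct) || pct < 0 || pct > 50) {
    stop("`pct` must be an inflation percentage in [0, 50]", call. = FALSE)
  }
  as.integer(ceiling(n_total * (1 + pct / 100)))
}

#' @export
print.samplesize_result <- function(x, ...) {
  cat(sprintf("Two-proportion %s design (%s framing)\n",
              x$hypothesis, x$framing))
  cat(sprintf("  proportions: control %.4g, new %.4g\n",
              x$p_control, x$p_new))
  if (x$hypothesis == "noninferiority") {
    cat(sprintf("  non-inferiority margin: %.4g (one-sided alpha %.3g)\n",
                x$margin, x$alpha))
  } else {
    cat(sprintf("  two-sided alpha: %.3g\n", x$alpha))
  }
  cat(sprintf("  power: %.3g   z-quantiles: %.6f (alpha), %.6f (power)\n",
              x$power, x$z_alpha, x$z_power))
  cat(sprintf("  unrounded n: %.3f\n", x$n_unrounded))
  cat(sprintf("  n per group: %d   total: %d\n", x$n_per_group, x$n_total))
  if (!is.na(x$n_inflated)) {
    cat(sprintf("  inflated %.3g%% for dropout: %d\n",
                x$inflate_pct, x$n_inflated))
  }
  invisible(x)
}
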