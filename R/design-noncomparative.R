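#' Allocate a total sample between cases and controls by prevalence
#'
#' Splits a planned total sample so that the case group (patients with the
#' target condition) mirrors the condition's prevalence in the target
#' population: `cases = round(total * prevalence)` with half-integers rounded
#' up, `controls = total - cases`. A degenerate allocation (either group
#' rounding to zero) is returned with a warning rather than an error.
#'
#' @param total Total planned sample size (positive integer).
#' @param prevalence Prevalence of the target condition, in (0, 1).
#' @return A list with integer `cases` and `controls` summing to `total`,
#'   plus a `warnings` character vector (empty when the split is proper).
#' @examples
#' allocate_by_prevalence(213, 0.6)  # 128 cases, 85 controls
#' allocate_by_prevalence(213, 0.1)  # 21 cases, 192 controls
#' @export
allocate_by_prevalence <- function(total, prevalence) {
  if (length(total) != 1L || !is.finite(total) || total < 1 ||
      total != round(total)) {
    stop("`total` must be a positive integer", call. = FALSE)
  }
  check_probability(prevalence, "prevalence", open = TRUE)
  cases <- as.integer(round_half_up(total * prevalence))
  controls <- as.integer(total) - cases
  warnings <- character(0)
  if (cases == 0L || controls == 0L) {
    warnings <- sprintf(
      "degenerate allocation: %s group is empty at prevalence %g",
      if (cases == 0L) "case" else "control", prevalence)
    warning(warnings, call. = FALSE)
  }
  list(cases = cases, controls = controls, warnings = warnings)
}

#' Size a non-comparative validation study of a diagnostic or predictive model
#'
#' Plans a single-test-versus-reference study in which the study succeeds if
#' the lower confidence bound of each of two alternative accuracy metrics
#' (typically PPV and NPV; which one is "primary" is the investigator's
#' choice — PPV for a confirmation/diagnosis task, NPV for screening — and is
#' only echoed in the report, never inferred) reaches a pre-set floor.
#'
#' For each metric the point estimate is assumed to sit at the midpoint
#' between its floor and 100% ([midpoint_estimate]), the smallest sample
#' achieving the floor is found by exact confidence-interval inversion
#' ([min_n_for_lower_bound]), the two per-metric sizes are summed, and the
#' total is split between cases and controls by prevalence
#' ([allocate_by_prevalence]).
#'
#' Because published worked values for this procedure are not always the
#' strict minima (calculators are often probed at candidate n), per-metric
#' sizes can also be supplied directly via `override_n`; the achieved
#' intervals are then reported at those sizes.
#'
#' @param target_lower_primary Floor (percent) for the primary metric's lower
#'   confidence bound.
#' @param target_lower_alternative Floor (percent) for the alternative
#'   metric's lower confidence bound.
#' @param level Confidence level in (0, 1).
#' @param prevalence Prevalence of the target condition in (0, 1).
#' @param override_n Optional length-2 integer vector of per-metric sample
#'   sizes `(primary, alternative)` to use instead of the computed minima.
#' @param primary_metric Label for the primary metric, `"ppv"` or `"npv"`;
#'   recorded in the result only.
#' @param inflate_pct Optional dropout inflation percentage applied to the
#'   total (see [inflate_for_dropout]).
#'
#' @return An object of class `"noncomp_design"`: a list with per-metric
#'   sizes `n_primary` / `n_alternative` and their achieved `cp_ci`
#'   intervals, `n_total`, the prevalence allocation `n_cases` / `n_controls`,
#'   `n_inflated` (or `NA`), and the echoed inputs.
#' @examples
#' # published worked example: floors 90% (PPV) and 80% (NPV),
#' # per-metric sizes 150 and 63 supplied, prevalence 60%
#' size_noncomparative(90, 80, prevalence = 0.6, override_n = c(150, 63))
#' @export
size_noncomparative <- function(target_lower_primary,
                                target_lower_alternative,
                                level = 0.95,
                                prevalence,
                                override_n = NULL,
                                primary_metric = c("ppv", "npv"),
                                inflate_pct = NULL) {
  primary_metric <- match.arg(primary_metric)
  check_probability(prevalence, "prevalence", open = TRUE)
  targets <- c(target_lower_primary, target_lower_alternative)
  if (any(targets >= 100)) {
    stop("target lower bounds must be below 100%", call. = FALSE)
  }

  points <- vapply(targets, midpoint_estimate, numeric(1))
  if (is.null(override_n)) {
    sol <- lapply(seq_along(targets), function(i) {
      min_n_for_lower_bound(points[i], targets[i], level)
    })
    ns <- vapply(sol, `[[`, integer(1), "n")
    cis <- lapply(sol, `[[`, "ci")
    policy <- "minimal"
  } else {
    if (length(override_n) != 2L || any(override_n < 1) ||
        any(override_n != round(override_n))) {
      stop("`override_n` must be two positive integers (primary, alternative)",
           call. = FALSE)
    }
    ns <- as.integer(override_n)
    cis <- lapply(seq_along(targets), function(i) {
      x <- round_half_up(points[i] / 100 * ns[i])
      clopper_pearson_ci(min(x, ns[i]), ns[i], level)
    })
    policy <- "override"
  }

  n_total <- sum(ns)
  alloc <- allocate_by_prevalence(n_total, prevalence)
  n_inflated <- if (is.null(inflate_pct)) NA_integer_ else {
    inflate_total(n_total, inflate_pct)
  }

  structure(
    list(target_lower_primary = target_lower_primary,
         target_lower_alternative = target_lower_alternative,
         point_primary = points[1], point_alternative = points[2],
         level = level, prevalence = prevalence,
         primary_metric = primary_metric, n_policy = policy,
         n_primary = ns[1], n_alternative = ns[2],
         ci_primary = cis[[1]], ci_alternative = cis[[2]],
         n_total = n_total,
         n_cases = alloc$cases, n_controls = alloc$controls,
         n_inflated = n_inflated,
         warnings = alloc$warnings),
    class = "noncomp_design"
  )
}

#' @export
print.noncomp_design <- function(x, ...) {
  alt <- if (x$primary_metric == "ppv") "npv" else "ppv"
  cat("Non-comparative validation design (confidence-interval inversion)\n")
  cat(sprintf("  confidence level: %g%%   per-metric n policy: %s\n",
              100 * x$level, x$n_policy))
  cat(sprintf(
    "  %s (primary)    : floor %g%%, point %g%%, n = %d, achieved CI (%.1f%%, %.1f%%)\n",
    toupper(x$primary_metric), x$target_lower_primary, x$point_primary,
    x$n_primary, 100 * x$ci_primary$lower, 100 * x$ci_primary$upper))
  cat(sprintf(
    "  %s (alternative): floor %g%%, point %g%%, n = %d, achieved CI (%.1f%%, %.1f%%)\n",
    toupper(alt), x$target_lower_alternative, x$point_alternative,
    x$n_alternative, 100 * x$ci_alternative$lower,
    100 * x$ci_alternative$upper))
  cat(sprintf("  total n = %d\n", x$n_total))
  cat(sprintf("  allocation at prevalence %g: %d cases / %d controls\n",
              x$prevalence, x$n_cases, x$n_controls))
  if (!is.na(x$n_inflated)) {
    cat(sprintf("  inflated for dropout: %d\n", x$n_inflated))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   - ", w, "\n", sep = "")
  }
  invisible(x)
}
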