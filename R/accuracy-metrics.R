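#' Diagnostic accuracy metrics from a 2x2 confusion table
#'
#' Given counts of true positives, false positives, false negatives and true
#' negatives (with the reference "gold standard" test defining truth),
#' computes sensitivity, specificity, positive and negative predictive
#' values, overall accuracy and balanced accuracy. Metrics whose denominator
#' is zero (e.g. PPV when the test made no positive calls) are reported as
#' `NA` — explicitly undefined, never silently 0 or 1.
#'
#' @param tp,fp,fn,tn Non-negative integer counts of true positives, false
#'   positives, false negatives and true negatives.
#' @return An object of class `"accuracy_metrics"`: a list with the four
#'   counts and `se`, `sp`, `ppv`, `npv`, `accuracy_overall`,
#'   `accuracy_balanced`, all proportions in \[0, 1\] or `NA` if undefined.
#' @examples
#' confusion_metrics(tp = 90, fp = 20, fn = 10, tn = 80)
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("confusion-table counts must be non-negative integers",
         call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("confusion table is empty (total = 0)", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  se <- ratio(tp, tp + fn)
  sp <- ratio(tn, tn + fp)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         se = se, sp = sp,
         ppv = ratio(tp, tp + fp),
         npv = ratio(tn, tn + fn),
         accuracy_overall = (tp + tn) / total,
         accuracy_balanced = (se + sp) / 2),
    class = "accuracy_metrics"
  )
}

#' @export
print.accuracy_metrics <- function(x, digits = 4, ...) {
  cat("Diagnostic accuracy metrics (reference test defines truth)\n")
  cat(sprintf("  counts: tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.*f", digits, v)
  cat(sprintf("  sensitivity (recall) : %s\n", fmt(x$se)))
  cat(sprintf("  specificity          : %s\n", fmt(x$sp)))
  cat(sprintf("  PPV (precision)      : %s\n", fmt(x$ppv)))
  cat(sprintf("  NPV                  : %s\n", fmt(x$npv)))
  cat(sprintf("  accuracy (overall)   : %s\n", fmt(x$accuracy_overall)))
  cat(sprintf("  accuracy (balanced)  : %s\n", fmt(x$accuracy_balanced)))
  invisible(x)
}

#' Prevalence-adjusted predictive values
#'
#' Predictive values depend on the prevalence of the target condition in the
#' population where the test will be used, not only on the test's intrinsic
#' sensitivity and specificity. These functions recompute PPV and NPV for an
#' arbitrary prevalence P by Bayes' rule:
#' \deqn{PPV = \frac{Se \cdot P}{Se \cdot P + (1 - Sp)(1 - P)}}
#' \deqn{NPV = \frac{Sp (1 - P)}{Sp (1 - P) + (1 - Se) P}}
#'
#' An uninformative test (Se = Sp = 0.5) returns the prevalence itself for
#' PPV and its complement for NPV. A zero denominator (e.g. `se = 0`,
#' `sp = 1` for PPV) leaves the value undefined and returns `NA` with a
#' warning.
#'
#' @param se Sensitivity in \[0, 1\].
#' @param sp Specificity in \[0, 1\].
#' @param prevalence Prevalence of the target condition, in (0, 1).
#' @return The adjusted predictive value (a probability), or `NA` when the
#'   denominator is zero.
#' @examples
#' ppv_adjusted(se = 0.9, sp = 0.8, prevalence = 0.1)  # 1/3
#' npv_adjusted(se = 0.9, sp = 0.8, prevalence = 0.1)  # 72/73
#' @export
ppv_adjusted <- function(se, sp, prevalence) {
  check_probability(se, "se")
  check_probability(sp, "sp")
  check_probability(prevalence, "prevalence", open = TRUE)
  den <- se * prevalence + (1 - sp) * (1 - prevalence)
  if (den == 0) {
    warning("PPV undefined: no positive calls expected at these parameters")
    return(NA_real_)
  }
  se * prevalence / den
}

#' @rdname ppv_adjusted
#' @export
npv_adjusted <- function(se, sp, prevalence) {
  check_probability(se, "se")
  check_probability(sp, "sp")
  check_probability(prevalence, "prevalence", open = TRUE)
  den <- sp * (1 - prevalence) + (1 - se) * prevalence
  if (den == 0) {
    warning("NPV undefined: no negative calls expected at these parameters")
    return(NA_real_)
  }
  sp * (1 - prevalence) / den
}
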