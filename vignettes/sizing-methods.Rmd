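---
title: "Sizing clinical validations of diagnostic and predictive models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing clinical validations of diagnostic and predictive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagsize)
```

## The problem

A diagnostic model (or a clinical decision support system built on one)
with a binary output is validated prospectively against a reference
("gold standard") test. Its performance is summarized by sensitivity,
specificity, and the predictive values PPV and NPV; the predictive
values are the clinically decisive quantities — the probability that a
positive (negative) call is right — and, unlike Se and Sp, they depend
on the prevalence of the condition in the population where the test
will be used. A study that is too small leaves the confidence intervals
for these proportions too wide to support any claim; a study that is
too large wastes patients and time. `diagsize` computes the required
sizes for the three standard designs and verifies them by simulation.

## Non-comparative designs: confidence-interval inversion

For a single new test, the protocol fixes a floor for the lower
confidence bound of each target metric — e.g. "the lower 95% bound of
PPV must be at least 90%". Since the metric's future point estimate is
unknown at planning time, it is assumed to sit at the midpoint between
the floor and 100% (`midpoint_estimate`; floor 90% → point 95%). This
is a planning heuristic, not a guarantee, and is poorly justified at
small n, where the exact interval is far from symmetric.

`min_n_for_lower_bound` then finds, by direct scan, the smallest n such
that the exact Clopper–Pearson interval for the expected success count
`round_half_up(point · n)` has its lower bound at or above the floor.
Three numerical conventions matter:

* **Exact intervals.** The Clopper–Pearson interval is used — the
  bounds invert the binomial tail sums, evaluated through the exact
  beta-quantile characterization (`qbeta(α/2, x, n−x+1)` and
  `qbeta(1−α/2, x+1, n−x)`), with the degenerate counts x = 0 and
  x = n pinned to bounds 0 and 1. Approximate intervals (Wald, Wilson,
  Agresti–Coull) are deliberately not offered as a sizing basis: the
  exact interval's conservatism (true coverage ≥ nominal, verified
  exhaustively in the tests for all n ≤ 25) is the property the design
  criterion leans on.
* **Half-up rounding of expected successes.** 0.95 · 150 = 142.5 is
  rounded to 143; this is the only convention that reproduces the
  reference interval (90.6%, 98.1%) at n = 150, so it is pinned
  package-wide (`round_half_up`), including in the prevalence
  allocation below.
* **Strict minimality vs probed sizes.** Because the expected success
  count is re-rounded at every n, the achieved lower bound is not
  monotone in n, and the strictly smallest qualifying n can be well
  below a size found by manually probing a calculator (for floor 90%
  at point 95%, the strict minimum is 127, while 150 also qualifies).
  Published worked designs often report probed sizes. The package
  therefore supports both policies: the default returns the strict
  minimum; `override_n` accepts externally chosen per-metric sizes and
  reports the achieved intervals at those sizes.

The sizes for the two alternative metrics (PPV and NPV) are summed —
each patient contributes to only one of the two column margins — and
the total is allocated between cases and controls as
`cases = round_half_up(total · prevalence)`, so the sample reproduces
the target population's prevalence. Which of PPV/NPV is "primary"
(diagnosis tasks weight PPV, screening tasks NPV) is a protocol choice
the user records; the package never infers it. A degenerate allocation
(either group empty after rounding) is reported with a warning rather
than an error, since tiny pilot totals can legitimately round that way.

```{r}
size_noncomparative(90, 80, prevalence = 0.6, override_n = c(150, 63))
```

One widely circulated worked value is knowingly not reproduced
digit-for-digit: for the NPV sizing at n = 63 the exact interval at
the implied count 57/63 is (80.4%, 96.4%), whereas the interval often
quoted alongside that design is (80.5%, 95.9%) — the count originally
entered into the calculator that produced it is unrecoverable. The
test suite asserts only what the design requires — that the lower
bound at n = 63 clears the 80% floor — and records the mismatch.

## Comparative designs: two-proportion normal approximation

For a new test compared with an old one (accuracy p_c vs p_n), or a
two-arm model-guided trial (success rates), the per-group size is the
unpooled normal-approximation formula without continuity correction:

* superiority, two-sided α:
  n = ⌈(z₁₋α/₂ + z_pow)² [p_c(1−p_c) + p_n(1−p_n)] / (p_n − p_c)²⌉
* non-inferiority with margin d > 0, one-sided α:
  n = ⌈(z₁₋α + z_pow)² [p_c(1−p_c) + p_n(1−p_n)] / (p_n − p_c + d)²⌉

with full-precision normal quantiles (z₀.₉₇₅ = 1.959964,
z₀.₉₅ = 1.644854, z₀.₉₀ = 1.281552) and ceiling rounding. This exact
variant — unpooled variance, no correction, two-sided α for
superiority but one-sided for non-inferiority — is the one that
reproduces all the reference worked sizes (263; 1097; 560; 538); a
continuity-corrected or pooled-variance formula does not, which is why
those variants are not offered. Defaults are α = 0.05 and power 0.90
(0.80 is the accepted minimum).

The `framing` argument separates the study logistics: a
cross-sectional diagnostic comparison applies index, comparator and
reference test to the *same* patients, so the study needs one sample of
`n_per_group`; a two-arm RCT needs `2 · n_per_group`. The unpaired
formula is used in both framings — no paired-data correction is
applied, matching the practice the package codifies; for genuinely
paired analyses this is conservative in typical positive-correlation
settings but is a documented approximation. Prediction-model inputs
stated as disease frequencies can be passed with `rates = "event"`,
which maps them to success rates (1 − p) before sizing. Only 1:1
allocation is supported; other ratios are rejected explicitly rather
than sized incorrectly.

Non-inferiority questions usually cost more patients than superiority
questions (1097 vs 263 per group in the defaults above), because the
margin d is typically chosen smaller than a clinically significant
superiority effect. This is a tendency of realistic designs, not a
theorem — a margin wider than the expected superiority effect reverses
it — so the package's tests verify it only on the worked example pairs.

Every design should additionally be inflated by 5–10% for dropouts
(`inflate_for_dropout`, ceiling rounding; capped at 50% on the premise
that a design expecting more loss needs redesigning, not inflating).

## Monte Carlo verification

`simulate_power` draws repeated binomial pairs at assumed true
proportions and applies the design's own decision rule: the
unpooled-variance z-test (two-sided for superiority; one-sided shifted
by the margin for non-inferiority). The exact match between the sizing
formula's variance and the simulated test's variance is deliberate —
verifying a size computed from one approximation with a different test
(e.g. Fisher's exact) would confound formula error with test choice.
Numerical details:

* the estimated variance is floored at 1e−12 before division so
  degenerate draws (an arm with all successes or all failures) yield a
  defined statistic: a zero observed difference then never rejects
  under superiority, while under non-inferiority the positive margin
  forces rejection — both boundary behaviours are deterministic and
  tested;
* reproducibility: results are a pure function of (seed, reps, design);
  the caller's RNG state is saved and restored;
* `power_curve` derives each size's sub-seed from the master seed and
  the size itself (`(seed · 40503 + n · 69069) mod 2³¹−1`), so the
  estimate at a given n is independent of the grid it sits in;
* Monte Carlo noise is reported as the binomial standard error
  `sqrt(p̂(1−p̂)/reps)`; at the 100,000 reps used in the verification
  suite this is under 0.001, so the ±0.02 agreement checked against
  nominal power is far above noise. Unit tests use 2,000–20,000 reps,
  enough for the ±0.01–0.02 tolerances they assert.

```{r}
d <- size_superiority(0.80, 0.90)
simulate_power(d, reps = 20000, seed = 101)
```

The simulation samples independent binomials — it emulates exactly the
unpaired two-group model the sizing formula assumes. Real validation
data can depart from it (paired test administration, clustered
recruitment, non-representative prevalence, reference-test error), so
a passing simulation confirms internal consistency of the design
arithmetic, not robustness to those departures.

## Scope and limitations

* Sizing targets the predictive values and accuracy as proportions;
  Se/Sp-targeted sizing, AUROC-based sizing, time-to-event endpoints,
  equivalence (two-sided margin) designs and unequal randomization are
  out of scope and rejected or absent by design.
* Confidence level defaults to 95% everywhere; 99% is available where
  stricter evidence is wanted.
* Zero-denominator metrics (e.g. PPV with no positive calls) are
  reported as undefined (`NA`), never coerced to 0 or 1.
* Percentages are the user-facing unit for metric floors (matching
  protocol idiom); all internal arithmetic is on [0, 1]. In config
  files, proportions are the default and `percent_convention` switches
  the proportion-scale fields, to keep silent 100× errors impossible.
* The inverse-CI search is capped (default n ≤ 100,000) and fails with
  the best bound found rather than looping: a floor placed too close
  to the assumed point estimate makes the required n explode.

Problem sizes in the shipped verification suite: exhaustive interval
checks to n = 30 (oracle agreement) and n = 25 (coverage on a 0.01
prevalence grid), allocation conservation to n = 10,000, and 100,000
simulation replicates per verified design — each chosen to pin the
property at the precision the design arithmetic claims.
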