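# diagsize

Sample-size determination for clinical trials that validate diagnostic
tests and predictive (clinical decision support) models with a binary
outcome.

Before a diagnostic model or a model-guided treatment strategy can be used
in care, a prospective study must show that its accuracy metrics —
sensitivity (Se), specificity (Sp), and above all the prevalence-dependent
positive and negative predictive values (PPV, NPV) — meet pre-specified
requirements. `diagsize` computes how many patients such a study needs,
for the three designs that cover most validations:

1. **Non-comparative** (one new test against the reference standard): the
   study succeeds if the lower bound of the exact Clopper–Pearson
   confidence interval for each target metric reaches a pre-set floor.
   The package inverts the exact interval — lower bound solving
   P(X ≥ x | n, p) = α/2, upper bound solving P(X ≤ x | n, p) = α/2 —
   to the smallest n achieving the floor, assuming the metric's point
   estimate sits midway between the floor and 100%. Sizes for the two
   alternative metrics (PPV and NPV) are summed and the total is split
   between cases and controls in proportion to disease prevalence.
2. **Comparative superiority** (new vs old test, or two-arm RCT):
   n = ⌈(z₁₋α/₂ + z_power)² · [p_c(1−p_c) + p_n(1−p_n)] / (p_n − p_c)²⌉
   per group, two-sided α, unpooled variance, no continuity correction.
3. **Comparative non-inferiority** ("not worse than the old test by more
   than a margin d"): n = ⌈(z₁₋α + z_power)² · [p_c(1−p_c) + p_n(1−p_n)] /
   (p_n − p_c + d)²⌉ per group, one-sided α.

Every computed size can be verified by Monte Carlo simulation of the
design's decision rule (`simulate_power`, `power_curve`), and 2×2
confusion tables can be converted to metrics with prevalence adjustment
of PPV/NPV by Bayes' rule (`confusion_metrics`, `ppv_adjusted`,
`npv_adjusted`).

## Worked example

Physicians require a lower 95% confidence bound of at least 90% for PPV
and 80% for NPV, with published per-metric sizes 150 and 63 and a disease
prevalence of 60%:

```r
library(diagsize)
size_noncomparative(90, 80, prevalence = 0.6, override_n = c(150, 63))
#> Non-comparative validation design (confidence-interval inversion)
#>   confidence level: 95%   per-metric n policy: override
#>   PPV (primary)    : floor 90%, point 95%, n = 150, achieved CI (90.6%, 98.1%)
#>   NPV (alternative): floor 80%, point 90%, n = 63, achieved CI (80.4%, 96.4%)
#>   total n = 213
#>   allocation at prevalence 0.6: 128 cases / 85 controls
```

150 patients make the PPV interval (90.6%, 98.1%) clear the 90% floor; 63
do the same for NPV; the 213 total is split 128 cases / 85 controls so the
sample mirrors the 60% prevalence. (Omit `override_n` to get the strictly
minimal sizes instead.)

A two-arm non-inferiority trial of a model-guided strategy expected to
match the control arm's 80% success rate within a 5% margin, inflated 10%
for dropout:

```r
inflate_for_dropout(
  size_noninferiority(0.80, 0.80, margin = 0.05, framing = "two-arm-rct"), 10)
#> Two-proportion noninferiority design (two-arm-rct framing)
#>   proportions: control 0.8, new 0.8
#>   non-inferiority margin: 0.05 (one-sided alpha 0.05)
#>   power: 0.9   z-quantiles: 1.644854 (alpha), 1.281552 (power)
#>   unrounded n: 1096.172
#>   n per group: 1097   total: 2194
#>   inflated 10% for dropout: 2414
```

1097 patients per arm (2194 total, 2414 after inflation) are needed —
far more than the 263 per arm a superiority design with a 10-point
expected improvement requires, the usual price of a non-inferiority
question.

## Command-line interface

A thin CLI wraps the same functions:

```sh
exec/diagsize ci --successes 143 --trials 150
exec/diagsize diag-noncomp --ppv-lower 90 --npv-lower 80 --prevalence 0.6 --override-n 150,63
exec/diagsize rct-noninf --p-control 0.80 --p-new 0.80 --margin 0.05 --json
exec/diagsize run --config design.yaml
```

Exit codes: 0 success, 2 validation error, 3 design not achievable.

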