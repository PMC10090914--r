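Package: diagsize
Title: Sample Size Determination for Clinical Validation of Diagnostic and
    Predictive Decision-Support Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes required sample sizes for clinical trials evaluating
    binary-outcome diagnostic tests and predictive decision-support models.
    Implements exact Clopper-Pearson binomial confidence intervals and their
    inversion to the smallest sample achieving a target lower confidence
    bound, prevalence-based case/control allocation, prevalence adjustment of
    predictive values, normal-approximation designs for superiority and
    non-inferiority comparisons of two proportions, dropout inflation, and
    Monte Carlo verification of empirical power and type I error for every
    computed size. Includes a command-line interface for study planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
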