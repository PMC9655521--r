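Package: dtacomb
Title: Diagnostic Accuracy of Paired Dichotomized Tests and Their Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and combining two dichotomized diagnostic
    tests measured on the same subjects against a binary disease state.
    Implements paired 2x2x2 cross-classification tables (including exact
    reconstruction from printed cell percentages by largest-remainder
    rounding), per-test accuracy panels with Clopper-Pearson intervals for
    sensitivity and specificity and Mercaldo-style prevalence-adjusted logit
    intervals for predictive values, believe-the-positive ("OR") and
    believe-the-negative ("AND") combination rules in empirical and
    conditional-independence forms, sequential subgroup analysis within one
    test's negatives, paired comparisons (McNemar chi-square for sensitivity
    and specificity, a weighted generalized score test for predictive values,
    a Z-test on log odds ratios, Cohen's kappa), post-test probability sweeps
    over a pre-test prevalence grid with linear-regression summaries, and a
    calibrated Gaussian-copula synthetic cohort generator so the entire
    pipeline can be exercised without patient data. The motivating
    application is vertebral fragility fracture prediction in postmenopausal
    women from the trabecular bone score (TBS) and lumbar-spine bone mineral
    density (LS-BMD), dichotomized at Youden-index cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
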