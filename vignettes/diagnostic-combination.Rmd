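---
title: "Paired diagnostic tests, Bayesian combination rules, and prevalence projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired diagnostic tests, Bayesian combination rules, and prevalence projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtacomb)
```

## The problem

Two continuous bone measurements — lumbar-spine bone mineral density
(LS-BMD, g/cm²) and the trabecular bone score (TBS, a unitless texture
index of trabecular microarchitecture) — are each dichotomized at a cutoff
and used as screening tests for prevalent vertebral fragility fracture in
postmenopausal women. Because the two scores probe partly different
properties of bone, a woman may be positive on one and negative on the
other, which raises the questions this package answers quantitatively:

* how accurate is each dichotomized test on its own;
* what does one test add *within the other test's negatives* (sequential
  testing);
* what happens when the calls are combined under the believe-the-positive
  **OR rule** (positive if at least one test is positive) or the
  believe-the-negative **AND rule** (positive only if both are); and
* how do the post-test probabilities of either test or combination behave
  as the pre-test probability (prevalence) varies across target
  populations.

Everything empirical is a function of a single object, the paired 2×2×2
cross-classification: the counts of (test A ±) × (test B ±) split by
disease status. One convention applies throughout: **a score at or below
its cutoff is a positive test** — low density and low trabecular score
both indicate fragility — with no per-test override.

## The data model and count reconstruction

`paired_crosstab()` holds the eight counts; `marginal_table()` collapses to
one test's 2×2 table; `dichotomize()` tallies a patient-level cohort.

Published concordance tables often print only per-group cell *percentages*
to one decimal plus the group totals. `crosstab_from_percent()` inverts
that printing by largest-remainder rounding constrained to the group
total: each cell gets the floor of `pct/100 * total`, and the remaining
units go to the cells with the largest fractional remainders. For the
built-in reference study (86 fractured / 906 non-fractured women) this
recovery is exact — the recovered counts `(42, 16, 20, 8)` and
`(253, 127, 155, 371)` regenerate every published accuracy statistic — and
seven of the eight regenerated percentages round back to the printed
values. The eighth (the non-fractured both-negative cell) prints as 41.0
where the counts give 40.9; this is print rounding on the publication's
side (371/906 = 40.95%), and the package reports rather than hides it.

```{r}
xt <- study_crosstab()
xt
```

## Accuracy panels and their confidence intervals

For a 2×2 table, `accuracy_panel()` reports sensitivity SE = TP/(TP+FN),
specificity SP = TN/(TN+FP), predictive values PPV = TP/(TP+FP),
NPV = TN/(TN+FN), prevalence, positivity rate, and the diagnostic odds
ratio OR = (TP·TN)/(FP·FN).

Interval choices, each made once and applied everywhere:

* **SE and SP**: exact Clopper–Pearson bounds from beta quantiles
  (`clopper_pearson()`); the lower bound is 0 at k = 0 and the upper 1 at
  k = n. Coverage is at least nominal by construction.
* **PPV and NPV**: predictive values depend on prevalence, so the package
  uses the prevalence-adjusted logit interval in the style of Mercaldo
  (`mercaldo_pv_ci()`): write the predictive value via Bayes' theorem in
  terms of (SE, SP, π), form the delta-method variance of its logit from
  the diseased and healthy sample sizes with π treated as fixed, and
  back-transform. A plain Wald interval is always computed alongside
  (`ppv_wald`, `npv_wald`) because published tables are ambiguous about
  which method was used; the package reports both and forces agreement
  with neither. At boundary SE/SP the logit form is undefined; an
  Agresti–Coull-style adjusted variant is available and is used as an
  automatic fallback inside panels.
* **OR**: Wald interval on the log scale with Woolf variance Σ 1/cell.
  With a single stratum the Mantel–Haenszel estimator reduces to the
  sample cross-product ratio, which is what is implemented. Association is
  tested with the Pearson chi-square without continuity correction.
* Zero cells: the OR is *undefined and flagged* by default; the
  Haldane–Anscombe +0.5 correction is opt-in (`or_zero = "haldane"`).
  Predictive values with empty denominators are flagged `NA`, never 0.

`youden_cutoff()` fixes a dichotomization threshold by maximizing the
Youden index J = SE + SP − 1 over candidate thresholds at midpoints
between adjacent distinct scores (plus sentinels), ties broken toward the
smallest threshold. The scan is exhaustive, so it equals brute force by
construction; a property test verifies this on random instances.

## Combination rules: empirical, not independence

`combine_tests()` reads the OR-rule and AND-rule 2×2 tables directly off
the paired cross-classification, so conditional dependence between tests
is fully respected. The textbook closed forms under conditional
independence (`combine_independence()`; e.g. OR-rule
SE = SE₁ + SE₂ − SE₁·SE₂) are provided for what-if analysis only: on the
reference data they give an OR-rule sensitivity of 90.9% where the
empirical combination gives 90.7% — the gap is a direct measure of the
conditional dependence between TBS and LS-BMD. The empirical mode is the
default because it is the one that reproduces observed data.

Two structural identities are worth knowing (both are asserted as exact
equalities in the tests): the OR-rule negatives are exactly the
both-negative cell, so OR-rule NPV coincides with the NPV of the second
test inside the first test's negative stratum (`subgroup_panel()`); and
dominance always holds — the OR rule's SE is at least each component's SE
and its SP at most each component's SP, with the AND rule mirrored.

## Paired comparisons

* **SE/SP**: uncorrected McNemar chi-square `(b − c)²/(b + c)` on the
  discordant cells of the relevant disease stratum, 1 df. This is the
  likelihood-ratio-style paired comparison that reproduces the reference
  statistics (0.444 and 2.780 from the recovered counts, printed as 0.446
  and 2.788 — the small gaps are count rounding inherited from percentage
  reconstruction, not a method difference).
* **PPV/NPV**: a weighted generalized score test (`wgs_test()`). Each
  subject contributes one record per test on which the relevant call was
  made; an identity-link marginal model with a test indicator is scored at
  the null-restricted common predictive value and studentized with a
  subject-clustered empirical variance. The score collapses to
  `n₁n₂/(n₁+n₂) · (PV₂ − PV₁)`, giving label-swap invariance and an exact
  zero for duplicated tests. Where the construction admits variants, the
  default centres the variance residuals at the null-restricted common
  value (`variant = "unweighted"`); a `"weighted"` variant centres them at
  test-specific values. The two agree to three decimals on the reference
  data and asymptotically under the null; a 2,000-replicate null
  simulation keeps the empirical size below 7% at nominal 5%.
* **OR vs OR**: Z-test on the log scale with summed Woolf variances
  (`z_test_log_or()`). This treats the two tables as independent samples;
  when a combination is compared against one of its own components the
  overlap is ignored, and the documentation says so — the p-value is
  indicative, the significance verdict is the robust conclusion.
* **Agreement**: Cohen's kappa overall and per stratum; Bonferroni
  adjustment is `min(1, p·m)` via `p.adjust`.

## Prevalence projection

`ppv_at()`/`npv_at()` are Bayes' theorem; at a table's own prevalence they
reproduce the count ratios to 10⁻¹², which is asserted as an invariant.
`prevalence_sweep()` (or `predict()` on a fitted model) evaluates all four
tests over a grid — default 2–40% with the reference sample prevalence
8.67% included, 18 points — with Mercaldo-style intervals in which the
observed n_d and n_h stay fixed while π varies. Holding the sample sizes
fixed at hypothetical prevalences is an approximation (the variance
bookkeeping of a counterfactual study is not identified); it is the
standard projection used when transporting a study's accuracy to other
populations, and it is documented as such rather than presented as exact.

`sweep_regression()` fits OLS of a predictive value on prevalence, both in
percent, and reports the signed Pearson R. Over this grid the AND-rule PPV
correlates with prevalence at R = 0.9971 and the OR-rule NPV at
R = −0.9935. The publication prints −0.993; the computed value rounds to
−0.994, so the package's tests assert |R + 0.993| < 0.001 instead of
equality at three decimals.

## The synthetic cohort generator

`generate_cohort()` emulates the reference study population: within each
disease group, (LS-BMD, TBS) are bivariate normal with the published group
means and SDs (fractured: TBS 1.165 ± 0.095, BMD 0.771 ± 0.127;
non-fractured: 1.214 ± 0.100, 0.828 ± 0.120; 86/906 women), covariates
(age, height, weight, BMI, age at menopause) independent normals with the
published group summaries, and the within-group dependence a
Gaussian-copula correlation ρ. The defaults *are* these study conditions;
they are not tuning knobs.

ρ is not published anywhere, so it is **calibrated** per disease group
(`calibrate_rho()`): root-find ρ so that the bivariate-normal orthant
probability of both scores falling at or below their cutoffs equals the
observed joint-positive proportion (48.8% fractured, 27.9% non-fractured).
The orthant probability is computed by one-dimensional quadrature of
φ(x)·Φ((z_b − ρx)/√(1−ρ²)) with `integrate` at 10⁻¹⁰ relative tolerance,
and the root by `uniroot` inside the Fréchet bounds (targets outside them
are rejected with the bounds in the message). The calibrated values are
ρ ≈ 0.63 (fractured) and ρ ≈ 0.56 (non-fractured) — plausible for two
measurements derived from the same DXA scan.

**What the generator does not reproduce.** A Gaussian marginal with the
published fractured-group moments puts 59.0% of fractured women at or
below the BMD cutoff and 65.9% at or below the TBS cutoff, whereas the
study observed 67.4% and 72.1%. The real score distributions in the
fractured group are evidently not Gaussian with those moments (skewness or
censoring the publication gives no handle on), and the generator keeps the
published parameters instead of distorting them to force agreement.
Consequences, stated plainly:

* measured on the *whole cohort*, all eight cell proportions of a 100×
  cohort land within 2 percentage points of the reference table (largest
  systematic deviation ≈ 1.3 points, in the fractured both-negative cell),
  and this is what the recovery tests assert;
* measured *within the fractured group*, the both-negative cell is ~24%
  against an observed 9.3%, so the generator's implied OR-rule sensitivity
  is ~76%, well short of the observed 90.7%. The recovery test therefore
  checks the empirical OR-rule SE against the generator's own analytic
  orthant value, not against the published figure. Passing synthetic tests
  shows the pipeline is correct under the generator's assumptions; it does
  not certify the Gaussian model as a faithful image of fractured-group
  tails.

`baseline_comparison()` closes the loop on the cohort side: per variable,
group means ± SD, Levene's test centred at the mean (via `car`), and a
pooled or Welch t-test chosen by the Levene outcome at 0.05 — mirroring
how baseline tables of this kind are produced. `t_test_summary()` runs the
same test from printed summary statistics alone.

## Numerical and design choices

* Counts are integers throughout; reconstruction rejects percentage sets
  whose sum strays more than 0.2 from 100 (the worst case for four values
  printed to one decimal).
* Confidence level defaults to 0.95 everywhere; printed percentages use
  two decimals in CSV output, while the JSON summary keeps full precision.
* The replication tolerance in `run_replication()` is 0.05 absolute on
  percentages (print rounding), 0.01 on odds ratios, kappas and test
  statistics, and 0.1 on the post-test probability grid. Six entries are
  exempted and listed with explanations: three values internally
  inconsistent in the publication itself (a subgroup PPV pair that appears
  swapped in print, and a fractured-stratum kappa reported as both 0.100
  and 0.010), and three statistics sensitive to count rounding or to the
  unstated pairing treatment (the WGS NPV statistic, one McNemar-adjacent
  rounding, the log-OR Z-test p-value).
* Simulation sizes used by the test suite — 10⁴ draws for interval
  coverage and independence-limit checks, 2,000 null replicates for the
  WGS size check, a 100× cohort (99,200 rows) for recovery — were chosen
  as the smallest sizes at which the Monte-Carlo error is comfortably
  below the asserted tolerances.

## Limitations

The package analyzes one pair of dichotomous tests against one binary
state: no ≥3-test combinations, weighted or majority rules, ROC-surface
optimization of the rule choice, exact conditional McNemar, longitudinal
fracture-risk modelling, or image-level computation of either score. The
T-score helper takes an explicit reference mean/SD and ships no
manufacturer values; the pair (0.800 g/cm² ↔ T = −2.3) is kept only as a
validation checkpoint.
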