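#' Combine two paired tests under the OR or AND rule
#'
#' The believe-the-positive "OR rule" calls the combination positive when at
#' least one component test is positive (raising sensitivity at the expense
#' of specificity); the believe-the-negative "AND rule" calls it positive
#' only when both are (raising specificity at the expense of sensitivity).
#' This is the empirical combination: the combined 2 x 2 table is read
#' directly off the paired cross-classification, so any conditional
#' dependence between the two tests is respected. For the closed-form
#' combination under assumed conditional independence see
#' [combine_independence()].
#'
#' @param x a [paired_crosstab()].
#' @param rule `"or"` or `"and"`.
#' @return A [binary_test_table()] for the combined test.
#' @examples
#' xt <- paired_crosstab(c(pp = 42, pn = 16, np = 20, nn = 8),
#'                       c(pp = 253, pn = 127, np = 155, nn = 371))
#' combine_tests(xt, "or")   # SE 78/86 = 90.70%
#' combine_tests(xt, "and")  # SP 653/906 = 72.08%
#' @export
combine_tests <- function(x, rule = c("or", "and")) {
  stopifnot(inherits(x, "paired_crosstab"))
  rule <- match.arg(rule)
  d <- x$diseased; h <- x$healthy
  lab <- paste0(x$test_a, " ", toupper(rule), " ", x$test_b)
  if (rule == "or") {
    binary_test_table(tp = sum(d) - d[["nn"]], fp = sum(h) - h[["nn"]],
                      fn = d[["nn"]], tn = h[["nn"]], label = lab)
  } else {
    binary_test_table(tp = d[["pp"]], fp = h[["pp"]],
                      fn = sum(d) - d[["pp"]], tn = sum(h) - h[["pp"]],
                      label = lab)
  }
}

#' Combined accuracy under conditional independence
#'
#' Closed-form sensitivity and specificity of the OR/AND combination when
#' the two tests are assumed conditionally independent given disease status:
#' for the OR rule `se = se1 + se2 - se1*se2` and `sp = sp1*sp2`; for the
#' AND rule `se = se1*se2` and `sp = sp1 + sp2 - sp1*sp2`. Real paired tests
#' are usually conditionally dependent, so these values generally differ
#' from the empirical combination of [combine_tests()]; the gap is itself a
#' useful measure of dependence.
#'
#' @param se1,sp1,se2,sp2 component accuracies in `[0, 1]`.
#' @param rule `"or"` or `"and"`.
#' @return Named numeric vector `c(se, sp)`.
#' @export
combine_independence <- function(se1, sp1, se2, sp2, rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(all(c(se1, sp1, se2, sp2) >= 0), all(c(se1, sp1, se2, sp2) <= 1))
  if (rule == "or") c(se = se1 + se2 - se1 * se2, sp = sp1 * sp2)
  else c(se = se1 * se2, sp = sp1 + sp2 - sp1 * sp2)
}

#' Accuracy of one test within the other's negative stratum
#'
#' Sequential-testing subgroup analysis: restricts the cohort to subjects
#' who tested negative on the conditioning test and evaluates the remaining
#' test there. The stratum prevalence is lower than the whole-sample
#' prevalence whenever the conditioning test has some sensitivity, which is
#' what makes the stratum the natural place to ask whether the second test
#' adds information. The negative predictive value of this stratum's test is
#' identical, by construction, to the NPV of the OR-rule combination: both
#' equal the both-negative healthy count over the both-negative total.
#'
#' Conditioning on the positive stratum is exposed for exploration
#' (`state = "positive"`) but is not part of the replication surface.
#'
#' @param x a [paired_crosstab()].
#' @param conditioning `"a"` or `"b"`: the test whose stratum is taken.
#' @param state stratum of the conditioning test, `"negative"` (default) or
#'   `"positive"`.
#' @param level confidence level for the inner accuracy panel.
#' @return An object of class `subgroup_dta`: list with the conditioning
#'   description, the inner [binary_test_table()], its [accuracy_panel()]
#'   and the stratum prevalence.
#' @examples
#' xt <- paired_crosstab(c(pp = 42, pn = 16, np = 20, nn = 8),
#'                       c(pp = 253, pn = 127, np = 155, nn = 371),
#'                       test_a = "LS-BMD", test_b = "TBS")
#' subgroup_panel(xt, conditioning = "a")  # TBS among LS-BMD-negatives
#' @export
subgroup_panel <- function(x, conditioning = c("a", "b"),
                           state = c("negative", "positive"), level = 0.95) {
  stopifnot(inherits(x, "paired_crosstab"))
  conditioning <- match.arg(conditioning)
  state <- match.arg(state)
  d <- x$diseased; h <- x$healthy
  # cells of the *other* test within the conditioning stratum
  pick <- function(g) {
    if (conditioning == "a" && state == "negative") c(pos = g[["np"]], neg = g[["nn"]])
    else if (conditioning == "a") c(pos = g[["pp"]], neg = g[["pn"]])
    else if (state == "negative") c(pos = g[["pn"]], neg = g[["nn"]])
    else c(pos = g[["pp"]], neg = g[["np"]])
  }
  dd <- pick(d); hh <- pick(h)
  if (sum(dd) + sum(hh) == 0L) stop("empty conditioning stratum")
  cond_label <- if (conditioning == "a") x$test_a else x$test_b
  inner_label <- if (conditioning == "a") x$test_b else x$test_a
  tab <- binary_test_table(tp = dd[["pos"]], fp = hh[["pos"]],
                           fn = dd[["neg"]], tn = hh[["neg"]],
                           label = sprintf("%s in %s-%s", inner_label,
                                           cond_label, state))
  if (sum(dd) == 0L || sum(hh) == 0L)
    stop("conditioning stratum lacks one disease group; accuracy undefined")
  structure(list(conditioning_test = cond_label, state = state,
                 inner_test = inner_label, table = tab,
                 panel = accuracy_panel(tab, level = level),
                 prevalence = sum(dd) / (sum(dd) + sum(hh)),
                 n = sum(dd) + sum(hh)),
            class = "subgroup_dta")
}

#' @export
print.subgroup_dta <- function(x, ...) {
  cat(sprintf("Subgroup: %s evaluated among %s-%s subjects (n = %d, prevalence %.2f%%)\n",
              x$inner_test, x$conditioning_test, x$state, x$n, 100 * x$prevalence))
  print(x$panel)
  invisible(x)
}
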