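#' Fit a paired diagnostic test accuracy model
#'
#' The package's central fitting function. Given either a paired
#' cross-classification or patient-level data (formula interface), it
#' evaluates both component tests, their believe-the-positive ("OR") and
#' believe-the-negative ("AND") combinations, the two sequential subgroup
#' analyses (each test within the other's negatives), Cohen's kappa overall
#' and by disease stratum, and the paired comparison battery.
#'
#' The formula interface takes `disease ~ score_a + score_b` with a
#' patient-level data frame; scores are dichotomized at the supplied
#' cutoffs (positive when the score is at or below its cutoff) or, when
#' `cutoffs = "youden"`, at the Youden-index-maximizing cutoff of each
#' score.
#'
#' @param x a [paired_crosstab()], or a formula `disease ~ score_a + score_b`.
#' @param ... further arguments passed to methods.
#' @return An object of class `paired_dta`: list with the crosstab, the four
#'   [accuracy_panel()]s (`a`, `b`, `or`, `and`), the two `subgroups`, the
#'   three kappa strata, the `comparisons` data frame, independence-form
#'   combination accuracies, the confidence `level`, and (formula interface)
#'   the cutoffs used.
#' @examples
#' xt <- paired_crosstab(c(pp = 42, pn = 16, np = 20, nn = 8),
#'                       c(pp = 253, pn = 127, np = 155, nn = 371),
#'                       test_a = "LS-BMD", test_b = "TBS")
#' fit <- paired_dta(xt)
#' fit
#' coef(fit)
#' predict(fit, prevalence = c(0.05, 0.2))
#' @export
paired_dta <- function(x, ...) UseMethod("paired_dta")

#' @rdname paired_dta
#' @param level confidence level (default 0.95).
#' @param pv_ci primary predictive-value interval, `"mercaldo"` or `"wald"`
#'   (see [accuracy_panel()]).
#' @param wgs_variant variance variant for [wgs_test()].
#' @export
paired_dta.paired_crosstab <- function(x, level = 0.95,
                                       pv_ci = "mercaldo",
                                       wgs_variant = "unweighted", ...) {
  ta <- marginal_table(x, "a"); tb <- marginal_table(x, "b")
  panels <- list(a = accuracy_panel(ta, level, pv_ci),
                 b = accuracy_panel(tb, level, pv_ci),
                 or = accuracy_panel(combine_tests(x, "or"), level, pv_ci),
                 and = accuracy_panel(combine_tests(x, "and"), level, pv_ci))
  subgroups <- list(a_negative = subgroup_panel(x, "a", level = level),
                    b_negative = subgroup_panel(x, "b", level = level))
  kappa <- list(all = cohens_kappa(x, "all"),
                diseased = cohens_kappa(x, "diseased"),
                healthy = cohens_kappa(x, "healthy"))
  indep <- list(
    or = combine_independence(panels$a$se$estimate, panels$a$sp$estimate,
                              panels$b$se$estimate, panels$b$sp$estimate, "or"),
    and = combine_independence(panels$a$se$estimate, panels$a$sp$estimate,
                               panels$b$se$estimate, panels$b$sp$estimate, "and"))
  structure(list(crosstab = x, panels = panels, subgroups = subgroups,
                 kappa = kappa, comparisons = compare_tests(x, wgs_variant),
                 independence = indep, level = level,
                 cutoffs = NULL, call = match.call()),
            class = "paired_dta")
}

#' @rdname paired_dta
#' @param data a patient-level data frame (formula interface).
#' @param cutoffs numeric length-2 vector (test A, test B), or `"youden"`.
#' @export
paired_dta.formula <- function(x, data, cutoffs = "youden", level = 0.95, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.pass)
  if (ncol(mf) != 3L)
    stop("formula must be `disease ~ score_a + score_b`")
  disease <- mf[[1]]
  score_a <- mf[[2]]; score_b <- mf[[3]]
  name_a <- names(mf)[2]; name_b <- names(mf)[3]
  if (identical(cutoffs, "youden")) {
    keep <- stats::complete.cases(mf)
    cut_a <- youden_cutoff(score_a[keep], disease[keep])
    cut_b <- youden_cutoff(score_b[keep], disease[keep])
    cutoffs <- c(cut_a$value, cut_b$value)
    cut_objs <- list(a = cut_a, b = cut_b)
  } else {
    if (length(cutoffs) != 2L) stop("`cutoffs` must be length 2 or \"youden\"")
    cut_objs <- NULL
  }
  cohort <- data.frame(disease = disease, a = score_a, b = score_b)
  xt <- dichotomize(cohort, cutoffs[1], cutoffs[2],
                    col_a = "a", col_b = "b", col_disease = "disease",
                    test_a = name_a, test_b = name_b)
  fit <- paired_dta(xt, level = level, ...)
  fit$cutoffs <- stats::setNames(cutoffs, c(name_a, name_b))
  fit$youden <- cut_objs
  fit$call <- match.call()
  fit
}

#' @export
print.paired_dta <- function(x, ...) {
  xt <- x$crosstab
  cat("Paired diagnostic test accuracy:", xt$test_a, "and", xt$test_b, "\n")
  cat(sprintf("  n = %d (%d diseased, %d healthy), prevalence %.2f%%\n",
              n_diseased(xt) + n_healthy(xt), n_diseased(xt), n_healthy(xt),
              100 * x$panels$a$prevalence))
  if (!is.null(x$cutoffs))
    cat("  cutoffs (positive if score <= cutoff):",
        paste(names(x$cutoffs), format(x$cutoffs, digits = 4), collapse = ", "), "\n")
  cat("\nAccuracy (proportions; see summary() for confidence intervals):\n")
  m <- coef(x)
  printCoefmat(m, digits = 4, cs.ind = integer(), tst.ind = integer(),
               P.values = FALSE, has.Pvalue = FALSE)
  cat(sprintf("\nCohen's kappa: %.3f overall (%.3f diseased, %.3f healthy)\n",
              x$kappa$all$kappa, x$kappa$diseased$kappa, x$kappa$healthy$kappa))
  invisible(x)
}

#' @export
coef.paired_dta <- function(object, ...) {
  p <- object$panels
  rows <- c(a = object$crosstab$test_a, b = object$crosstab$test_b,
            or = "OR rule", and = "AND rule")
  m <- t(vapply(names(rows), function(k) {
    pk <- p[[k]]
    c(se = pk$se$estimate, sp = pk$sp$estimate,
      ppv = pk$ppv$estimate, npv = pk$npv$estimate,
      odds_ratio = pk$odds_ratio$estimate)
  }, numeric(5)))
  rownames(m) <- unname(rows)
  m
}

#' @export
summary.paired_dta <- function(object, ...) {
  structure(list(fit = object), class = "summary.paired_dta")
}

#' @export
print.summary.paired_dta <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPanels:\n")
  for (k in names(fit$panels)) { print(fit$panels[[k]]); cat("\n") }
  cat("Subgroup analyses:\n")
  for (s in fit$subgroups) { print(s); cat("\n") }
  cat("Conditional-independence combination (reference only):\n")
  cat(sprintf("  OR rule:  se %.4f sp %.4f   AND rule: se %.4f sp %.4f\n",
              fit$independence$or[["se"]], fit$independence$or[["sp"]],
              fit$independence$and[["se"]], fit$independence$and[["sp"]]))
  cat("\nPaired comparisons (Bonferroni over the family):\n")
  cmp <- fit$comparisons
  cmp$statistic <- signif(cmp$statistic, 4)
  print(cmp, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Post-test probabilities of a fitted paired model
#'
#' Sweeps PPV and NPV of the two tests and both combination rules over a
#' prevalence grid, with Mercaldo-style intervals anchored at the fitted
#' sample sizes. This is the prevalence-projection step: the fitted
#' sensitivities and specificities are held fixed while the pre-test
#' probability varies.
#'
#' @param object a [paired_dta()] fit.
#' @param prevalence grid of pre-test probabilities; default
#'   [default_prevalence_grid()].
#' @param tests subset of `c("a", "b", "or", "and")`.
#' @param level confidence level (defaults to the fit's).
#' @param ... unused.
#' @return A [prevalence_sweep()] curve.
#' @export
predict.paired_dta <- function(object, prevalence = default_prevalence_grid(),
                               tests = c("a", "b", "or", "and"),
                               level = object$level, ...) {
  tests <- match.arg(tests, several.ok = TRUE)
  short <- c(a = object$crosstab$test_a, b = object$crosstab$test_b,
             or = "OR rule", and = "AND rule")
  tab <- do.call(rbind, lapply(tests, function(k) {
    pk <- object$panels[[k]]
    data.frame(label = unname(short[k]), se = pk$se$estimate, sp = pk$sp$estimate)
  }))
  prevalence_sweep(tab, grid = prevalence,
                   n_d = object$panels$a$n_d, n_h = object$panels$a$n_h,
                   level = level)
}

#' @export
plot.paired_dta <- function(x, target = c("both", "ppv", "npv"),
                            prevalence = default_prevalence_grid(), ...) {
  target <- match.arg(target)
  curve <- predict(x, prevalence = prevalence)
  if (target == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
    plot(curve, "ppv", ...)
    plot(curve, "npv", ...)
  } else plot(curve, target, ...)
  invisible(x)
}

#' Simulate paired crosstabs from a fitted model
#'
#' Parametric resampling: per disease group, cell counts are drawn from a
#' multinomial with the fitted cell proportions and the observed group
#' size. Useful for bootstrap-style uncertainty checks on derived
#' statistics.
#'
#' @param object a [paired_dta()] fit.
#' @param nsim number of crosstabs.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` [paired_crosstab()] objects.
#' @export
simulate.paired_dta <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  xt <- object$crosstab
  nd <- n_diseased(xt); nh <- n_healthy(xt)
  pd <- xt$diseased / nd; ph <- xt$healthy / nh
  lapply(seq_len(nsim), function(i) {
    paired_crosstab(stats::setNames(as.vector(stats::rmultinom(1, nd, pd)), cell_names),
                    stats::setNames(as.vector(stats::rmultinom(1, nh, ph)), cell_names),
                    test_a = xt$test_a, test_b = xt$test_b)
  })
}
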