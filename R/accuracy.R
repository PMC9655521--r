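#' Diagnostic accuracy panel for a 2 x 2 table
#'
#' Computes the full accuracy summary of one dichotomous test against
#' disease: sensitivity and specificity with exact Clopper-Pearson
#' intervals, positive and negative predictive values at the table's own
#' prevalence with both Mercaldo-style prevalence-adjusted logit intervals
#' and plain Wald intervals, the diagnostic odds ratio with a Wald interval
#' on the log scale, and the Pearson chi-square test of association (no
#' continuity correction).
#'
#' Predictive values with a zero denominator (no positive or no negative
#' calls) are flagged as undefined rather than silently reported as zero.
#' A zero cell makes the odds ratio undefined under the default policy;
#' `or_zero = "haldane"` instead adds 0.5 to every cell (Haldane-Anscombe)
#' before forming the ratio and its interval.
#'
#' @param tab a [binary_test_table()].
#' @param level confidence level (default 0.95).
#' @param pv_ci which interval to report as the primary `ppv`/`npv` entry:
#'   the Mercaldo logit interval (default, the method intended for
#'   predictive values under an assumed prevalence) or the Wald interval.
#'   Both are always available as `ppv_mercaldo`/`ppv_wald` etc.
#' @param or_zero policy for zero cells in the odds ratio: `"undefined"`
#'   (default; `NA` with a flag) or `"haldane"` (0.5 added to each cell).
#' @return An object of class `accuracy_panel`: a list with
#'   [proportion_ci()] entries `se`, `sp`, `ppv`, `npv` (plus the
#'   `*_mercaldo` / `*_wald` twins), an `odds_ratio` list (`estimate`,
#'   `lower`, `upper`, `statistic`, `p_value`), `prevalence`,
#'   `positivity_rate`, sample sizes and a character vector `flags`.
#' @examples
#' tbs <- binary_test_table(tp = 62, fp = 408, fn = 24, tn = 498, label = "TBS")
#' accuracy_panel(tbs)
#' @export
accuracy_panel <- function(tab, level = 0.95,
                           pv_ci = c("mercaldo", "wald"),
                           or_zero = c("undefined", "haldane")) {
  stopifnot(inherits(tab, "binary_test_table"))
  pv_ci <- match.arg(pv_ci)
  or_zero <- match.arg(or_zero)
  tp <- tab$tp; fp <- tab$fp; fn <- tab$fn; tn <- tab$tn
  n_d <- tp + fn; n_h <- fp + tn; n <- n_d + n_h
  if (n_d == 0 || n_h == 0)
    stop("both diseased and healthy subjects are required")
  flags <- character()

  se <- clopper_pearson(tp, n_d, level)
  sp <- clopper_pearson(tn, n_h, level)
  prevalence <- n_d / n
  positivity <- (tp + fp) / n

  # predictive values from the counts themselves
  ppv_est <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv_est <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  if (is.na(ppv_est)) flags <- c(flags, "ppv undefined: no positive calls")
  if (is.na(npv_est)) flags <- c(flags, "npv undefined: no negative calls")

  ppv_wald <- if (is.na(ppv_est)) proportion_ci(NA_real_, method = "wald")
              else wald_ci(tp, tp + fp, level)
  npv_wald <- if (is.na(npv_est)) proportion_ci(NA_real_, method = "wald")
              else wald_ci(tn, tn + fn, level)
  merc <- tryCatch(
    mercaldo_pv_ci(se$estimate, sp$estimate, n_d, n_h, prevalence, level),
    error = function(e) {
      tryCatch(mercaldo_pv_ci(se$estimate, sp$estimate, n_d, n_h, prevalence,
                              level, adjusted = TRUE),
               error = function(e2) list(ppv = proportion_ci(ppv_est, method = "mercaldo_logit"),
                                         npv = proportion_ci(npv_est, method = "mercaldo_logit")))
    })
  # at the table's own prevalence the Bayes form must agree with the counts;
  # keep the count-based point estimate (NA when undefined) with logit bounds
  ppv_merc <- merc$ppv; npv_merc <- merc$npv
  ppv_merc$estimate <- ppv_est
  npv_merc$estimate <- npv_est

  odds <- odds_ratio_stats(tp, fp, fn, tn, level, or_zero)
  flags <- c(flags, odds$flags)

  structure(list(
    label = tab$label, table = tab, n_d = n_d, n_h = n_h,
    prevalence = prevalence, positivity_rate = positivity,
    se = se, sp = sp,
    ppv = if (pv_ci == "mercaldo") ppv_merc else ppv_wald,
    npv = if (pv_ci == "mercaldo") npv_merc else npv_wald,
    ppv_mercaldo = ppv_merc, npv_mercaldo = npv_merc,
    ppv_wald = ppv_wald, npv_wald = npv_wald,
    odds_ratio = odds$or, level = level, flags = flags
  ), class = "accuracy_panel")
}

odds_ratio_stats <- function(tp, fp, fn, tn, level, or_zero) {
  flags <- character()
  cells <- c(tp, fp, fn, tn)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (any(cells == 0)) {
    if (or_zero == "undefined") {
      flags <- "odds ratio undefined: zero cell (set or_zero = \"haldane\" to correct)"
      warning("odds ratio undefined with a zero cell; returning NA")
      or <- list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                 statistic = NA_real_, p_value = NA_real_, correction = "none")
      return(list(or = or, flags = flags))
    }
    cells <- cells + 0.5
    flags <- "odds ratio: Haldane-Anscombe 0.5 correction applied"
  }
  est <- cells[1] * cells[4] / (cells[2] * cells[3])
  se_log <- sqrt(sum(1 / cells))
  chi <- suppressWarnings(
    stats::chisq.test(matrix(c(tp, fp, fn, tn), 2, byrow = TRUE), correct = FALSE))
  list(or = list(estimate = est,
                 lower = exp(log(est) - z * se_log),
                 upper = exp(log(est) + z * se_log),
                 statistic = unname(chi$statistic),
                 p_value = chi$p.value,
                 correction = if (length(flags)) "haldane" else "none"),
       flags = flags)
}

#' @export
print.accuracy_panel <- function(x, ...) {
  cat("Diagnostic accuracy:", x$label, "\n")
  cat(sprintf("  n diseased %d, n healthy %d; prevalence %.2f%%; positive calls %.2f%%\n",
              x$n_d, x$n_h, 100 * x$prevalence, 100 * x$positivity_rate))
  cat("  SE %:  ", format(x$se), "\n")
  cat("  SP %:  ", format(x$sp), "\n")
  cat("  PPV %: ", format(x$ppv), paste0("[", x$ppv$method, "]"), "\n")
  cat("  NPV %: ", format(x$npv), paste0("[", x$npv$method, "]"), "\n")
  or <- x$odds_ratio
  if (is.na(or$estimate)) {
    cat("  OR:    undefined\n")
  } else {
    cat(sprintf("  OR:    %.2f (%.2f-%.2f), chi-square %.2f, p %s\n",
                or$estimate, or$lower, or$upper, or$statistic,
                format.pval(or$p_value, digits = 3, eps = 1e-4)))
  }
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' @export
as.data.frame.accuracy_panel <- function(x, ...) {
  row <- function(q, ci) data.frame(quantity = q, estimate = ci$estimate,
                                    lower = ci$lower, upper = ci$upper,
                                    method = ci$method)
  out <- rbind(row("se", x$se), row("sp", x$sp),
               row("ppv", x$ppv_mercaldo), row("npv", x$npv_mercaldo),
               row("ppv_wald", x$ppv_wald), row("npv_wald", x$npv_wald),
               data.frame(quantity = "odds_ratio", estimate = x$odds_ratio$estimate,
                          lower = x$odds_ratio$lower, upper = x$odds_ratio$upper,
                          method = "wald_log"),
               data.frame(quantity = "prevalence", estimate = x$prevalence,
                          lower = NA, upper = NA, method = "point"),
               data.frame(quantity = "positivity_rate", estimate = x$positivity_rate,
                          lower = NA, upper = NA, method = "point"))
  out$label <- x$label
  out
}

#' Youden-index cutoff for a continuous score
#'
#' Selects the dichotomization threshold maximizing the Youden index
#' `J = SE + SP - 1` under the positivity convention *score <= threshold is
#' positive*. Candidate thresholds are the midpoints between adjacent
#' distinct observed scores plus sentinels below the minimum and above the
#' maximum; ties in `J` are broken by the smallest threshold.
#'
#' @param scores numeric vector of finite score values.
#' @param labels 0/1 disease indicators, same length as `scores`.
#' @return An object of class `diagnostic_cutoff`: list with `value`,
#'   `youden_j`, and the `se`/`sp` attained at the cutoff.
#' @examples
#' youden_cutoff(c(1, 2, 3, 4), c(1, 1, 0, 0))  # midpoint 2.5, J = 1
#' @export
youden_cutoff <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  keep <- !(is.na(scores) | is.na(labels))
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_d <- sum(labels == 1); n_h <- sum(labels == 0)
  if (n_d == 0 || n_h == 0) stop("both classes must be present to place a cutoff")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- list(j = -Inf)
  for (t in cand) {
    pos <- scores <= t
    se <- sum(pos & labels == 1) / n_d
    sp <- sum(!pos & labels == 0) / n_h
    j <- se + sp - 1
    if (j > best$j + 1e-12) best <- list(j = j, value = t, se = se, sp = sp)
  }
  structure(list(value = best$value, youden_j = best$j,
                 se = best$se, sp = best$sp),
            class = "diagnostic_cutoff")
}

#' @export
print.diagnostic_cutoff <- function(x, ...) {
  cat(sprintf("Youden cutoff %.4g (positive if score <= cutoff): J = %.3f (SE %.1f%%, SP %.1f%%)\n",
              x$value, x$youden_j, 100 * x$se, 100 * x$sp))
  invisible(x)
}
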