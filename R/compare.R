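#' Paired McNemar comparison of sensitivity or specificity
#'
#' Compares the two tests' sensitivity (within the diseased stratum) or
#' specificity (within the healthy stratum) using the uncorrected McNemar
#' chi-square on the stratum's discordant cells: `(b - c)^2 / (b + c)` with
#' one degree of freedom, where `b` and `c` count subjects on which exactly
#' one of the two tests makes the correct call. No continuity correction is
#' applied. When there is no discordance the statistic is defined as 0 with
#' `p = 1` and flagged.
#'
#' @param x a [paired_crosstab()].
#' @param target `"se"` or `"sp"`.
#' @return An object of class `test_comparison` with fields `comparison`,
#'   `statistic`, `df`, `p_value`, discordant counts `b`, `c`, and `flags`.
#' @examples
#' xt <- paired_crosstab(c(pp = 42, pn = 16, np = 20, nn = 8),
#'                       c(pp = 253, pn = 127, np = 155, nn = 371))
#' mcnemar_paired(xt, "se")  # (20-16)^2/36 = 0.444
#' @export
mcnemar_paired <- function(x, target = c("se", "sp")) {
  stopifnot(inherits(x, "paired_crosstab"))
  target <- match.arg(target)
  if (target == "se") {
    b <- x$diseased[["np"]]  # A-, B+ : only B correct
    c_ <- x$diseased[["pn"]] # A+, B- : only A correct
  } else {
    b <- x$healthy[["pn"]]   # A+, B- : only B correct (negative)
    c_ <- x$healthy[["np"]]  # A-, B+ : only A correct
  }
  flags <- character()
  if (b + c_ == 0) {
    stat <- 0; p <- 1; flags <- "no discordance"
  } else {
    stat <- (b - c_)^2 / (b + c_)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  new_test_comparison(paste0("mcnemar_", target), stat, 1L, p,
                      extra = list(b = b, c = c_), flags = flags)
}

new_test_comparison <- function(comparison, statistic, df, p_value,
                                extra = list(), flags = character()) {
  structure(c(list(comparison = comparison, statistic = statistic,
                   df = df, p_value = p_value, flags = flags), extra),
            class = "test_comparison")
}

#' @export
print.test_comparison <- function(x, ...) {
  lab <- if (!is.null(x$df) && !is.na(x$df)) sprintf("chi-square(%d)", x$df) else "Z"
  cat(sprintf("%s: %s = %.4g, p = %s\n", x$comparison, lab, x$statistic,
              format.pval(x$p_value, digits = 3, eps = 1e-6)))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Weighted generalized score test for paired predictive values
#'
#' Tests equality of the two tests' positive (or negative) predictive values
#' on paired data. Each subject contributes one record per test on which the
#' relevant call was made (a positive call for PPV, a negative call for
#' NPV); a marginal identity-link model for the disease outcome with a
#' test indicator is scored at the common null predictive value, and the
#' score is studentized with a cluster-robust (subject-level) empirical
#' variance. The score reduces to
#' `n1*n2/(n1+n2) * (PV2 - PV1)`, so the statistic is invariant to swapping
#' the test labels and is exactly zero when one test duplicates the other.
#'
#' Under the default `variant = "unweighted"` the residuals entering the
#' variance are centred at the null-restricted common predictive value; the
#' `"weighted"` variant centres concordant-call residuals at the average of
#' the two test-specific predictive values and discordant-call residuals at
#' the corresponding test's own value, which re-weights the variance when
#' positivity rates are unbalanced. The two variants agree asymptotically
#' under the null and differ negligibly in well-filled tables.
#'
#' @param x a [paired_crosstab()].
#' @param target `"ppv"` or `"npv"`.
#' @param variant variance construction, `"unweighted"` (default) or
#'   `"weighted"`.
#' @return A `test_comparison` (chi-square, 1 df) carrying the two
#'   predictive values as `pv1`, `pv2`.
#' @examples
#' xt <- paired_crosstab(c(pp = 42, pn = 16, np = 20, nn = 8),
#'                       c(pp = 253, pn = 127, np = 155, nn = 371))
#' wgs_test(xt, "ppv")
#' wgs_test(xt, "npv")
#' @export
wgs_test <- function(x, target = c("ppv", "npv"),
                     variant = c("unweighted", "weighted")) {
  stopifnot(inherits(x, "paired_crosstab"))
  target <- match.arg(target)
  variant <- match.arg(variant)
  d <- x$diseased; h <- x$healthy

  # Re-express as: outcome D, call indicators X1, X2 per subject.
  # For PPV: call = positive test, D = diseased.
  # For NPV: call = negative test, D = healthy (NPV is P(healthy | negative)).
  if (target == "ppv") {
    cells <- rbind(
      c(D = 1, X1 = 1, X2 = 1, m = d[["pp"]]), c(1, 1, 0, d[["pn"]]),
      c(1, 0, 1, d[["np"]]), c(1, 0, 0, d[["nn"]]),
      c(0, 1, 1, h[["pp"]]), c(0, 1, 0, h[["pn"]]),
      c(0, 0, 1, h[["np"]]), c(0, 0, 0, h[["nn"]]))
  } else {
    cells <- rbind(
      c(D = 1, X1 = 1, X2 = 1, m = h[["nn"]]), c(1, 1, 0, h[["np"]]),
      c(1, 0, 1, h[["pn"]]), c(1, 0, 0, h[["pp"]]),
      c(0, 1, 1, d[["nn"]]), c(0, 1, 0, d[["np"]]),
      c(0, 0, 1, d[["pn"]]), c(0, 0, 0, d[["pp"]]))
  }
  D <- cells[, 1]; X1 <- cells[, 2]; X2 <- cells[, 3]; m <- cells[, 4]
  n1 <- sum(m * X1); n2 <- sum(m * X2)
  if (n1 == 0 || n2 == 0)
    stop(toupper(target), " undefined for one test: no ",
         if (target == "ppv") "positive" else "negative", " calls")
  pv1 <- sum(m * X1 * D) / n1
  pv2 <- sum(m * X2 * D) / n2
  w <- n2 / (n1 + n2)
  phat <- (sum(m * X1 * D) + sum(m * X2 * D)) / (n1 + n2)
  U <- n1 * n2 / (n1 + n2) * (pv2 - pv1)
  hX <- X2 - w * (X1 + X2)
  centre <- if (variant == "unweighted") rep(phat, length(D)) else {
    ifelse(X1 == 1 & X2 == 1, (pv1 + pv2) / 2, ifelse(X2 == 1, pv2, pv1))
  }
  V <- sum(m * (hX * (D - centre))^2)
  if (V <= 0) {
    stat <- 0; p <- 1; flags <- "degenerate variance: identical calls"
  } else {
    stat <- U^2 / V
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    flags <- character()
  }
  new_test_comparison(paste0("wgs_", target), stat, 1L, p,
                      extra = list(pv1 = pv1, pv2 = pv2, variant = variant),
                      flags = flags)
}

#' Z-test comparing two odds ratios on the log scale
#'
#' `Z = (log OR1 - log OR2) / sqrt(V1 + V2)` with `Vi` the Woolf variance
#' `sum(1/cell)` of each table, two-sided normal p-value. This is an
#' independent-samples approximation; when the two tables share subjects
#' (as when comparing a combination rule against one of its components) the
#' true sampling covariance is ignored, so treat the p-value as indicative.
#'
#' @param t1,t2 [binary_test_table()] objects with all cells positive (or
#'   `correction = TRUE` to add 0.5 to every cell of a table containing a
#'   zero).
#' @param correction apply the Haldane-Anscombe correction to zero cells.
#' @return A `test_comparison` with a Z `statistic` (`df = NA`).
#' @export
z_test_log_or <- function(t1, t2, correction = FALSE) {
  stopifnot(inherits(t1, "binary_test_table"), inherits(t2, "binary_test_table"))
  get <- function(t) {
    cells <- c(t$tp, t$fp, t$fn, t$tn)
    if (any(cells == 0)) {
      if (!correction) stop("zero cell in table `", t$label,
                            "`; set correction = TRUE")
      cells <- cells + 0.5
    }
    c(lor = log(cells[1] * cells[4] / (cells[2] * cells[3])), v = sum(1 / cells))
  }
  a <- get(t1); b <- get(t2)
  z <- (a[["lor"]] - b[["lor"]]) / sqrt(a[["v"]] + b[["v"]])
  new_test_comparison(sprintf("z_log_or: %s vs %s", t1$label, t2$label),
                      z, NA_integer_, 2 * stats::pnorm(-abs(z)))
}

#' Cohen's kappa between the two tests' calls
#'
#' Chance-corrected agreement between the two dichotomous classifications,
#' computed on the pooled sample or within one disease stratum.
#'
#' @param x a [paired_crosstab()].
#' @param stratum `"all"`, `"diseased"` or `"healthy"`.
#' @return An object of class `agreement_result`: list with `kappa`,
#'   observed agreement `p_o`, expected agreement `p_e`, `n` and the
#'   stratum label. `kappa` is `NA` (flagged) when both tests are constant.
#' @examples
#' xt <- paired_crosstab(c(pp = 42, pn = 16, np = 20, nn = 8),
#'                       c(pp = 253, pn = 127, np = 155, nn = 371))
#' cohens_kappa(xt)              # 0.355
#' cohens_kappa(xt, "healthy")   # 0.367
#' @export
cohens_kappa <- function(x, stratum = c("all", "diseased", "healthy")) {
  stopifnot(inherits(x, "paired_crosstab"))
  stratum <- match.arg(stratum)
  cells <- switch(stratum,
                  all = x$diseased + x$healthy,
                  diseased = x$diseased,
                  healthy = x$healthy)
  n <- sum(cells)
  if (n == 0) stop("empty stratum `", stratum, "`")
  p_o <- (cells[["pp"]] + cells[["nn"]]) / n
  pa_pos <- (cells[["pp"]] + cells[["pn"]]) / n  # test A positive rate
  pb_pos <- (cells[["pp"]] + cells[["np"]]) / n
  p_e <- pa_pos * pb_pos + (1 - pa_pos) * (1 - pb_pos)
  flags <- character()
  kappa <- if (p_e >= 1 - 1e-12) {
    flags <- "kappa undefined: both tests constant"
    NA_real_
  } else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n = n,
                 stratum = stratum, flags = flags),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s, n = %d): %.3f (observed %.3f, expected %.3f)\n",
              x$stratum, x$n, x$kappa, x$p_o, x$p_e))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Bonferroni adjustment for a family of comparisons
#'
#' `min(1, p * m)` elementwise, delegated to [stats::p.adjust()] with the
#' family size `m` (which may exceed the number of p-values supplied).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m family size, at least `length(p)`.
#' @return Adjusted p-values, order-preserving.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= length(p)")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' All paired comparisons for a crosstab
#'
#' Convenience wrapper running the comparison battery used by
#' [paired_dta()]: McNemar for SE and SP, the weighted generalized score
#' test for PPV and NPV (test A vs test B), and log-OR Z-tests of each
#' combination rule against each component test. Bonferroni-adjusted
#' p-values are added over the whole family.
#'
#' @param x a [paired_crosstab()].
#' @param variant passed to [wgs_test()].
#' @return A data frame with one row per comparison: `comparison`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`, `verdict_at_0.05`.
#' @export
compare_tests <- function(x, variant = "unweighted") {
  stopifnot(inherits(x, "paired_crosstab"))
  ta <- marginal_table(x, "a"); tb <- marginal_table(x, "b")
  tor <- combine_tests(x, "or"); tand <- combine_tests(x, "and")
  res <- list(
    mcnemar_paired(x, "se"), mcnemar_paired(x, "sp"),
    wgs_test(x, "ppv", variant), wgs_test(x, "npv", variant),
    z_test_log_or(tor, ta), z_test_log_or(tor, tb),
    z_test_log_or(tand, ta), z_test_log_or(tand, tb))
  out <- do.call(rbind, lapply(res, function(r)
    data.frame(comparison = r$comparison, statistic = r$statistic,
               df = if (is.null(r$df)) NA_integer_ else r$df,
               p_value = r$p_value)))
  out$p_adjusted <- bonferroni_adjust(out$p_value, nrow(out))
  out$verdict_at_0.05 <- ifelse(out$p_value < 0.05, "significant", "ns")
  out
}
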