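#' Construct a proportion with confidence interval
#'
#' Lightweight container used throughout the package for sensitivity,
#' specificity, predictive values and rates.
#'
#' @param estimate,lower,upper proportions in `[0, 1]` (`NA` when undefined).
#' @param level confidence level.
#' @param method tag: `"clopper_pearson"`, `"wald"` or `"mercaldo_logit"`.
#' @return An object of class `proportion_ci`.
#' @keywords internal
#' @export
proportion_ci <- function(estimate, lower = NA_real_, upper = NA_real_,
                          level = 0.95, method = "none") {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 level = level, method = method),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.2f%% (%d%% CI: %.2f-%.2f, %s)\n",
              100 * x$estimate, round(100 * x$level),
              100 * x$lower, 100 * x$upper, x$method))
  invisible(x)
}

#' @export
format.proportion_ci <- function(x, digits = 2, ...) {
  if (is.na(x$estimate)) return("undefined")
  sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
          100 * x$estimate, 100 * x$lower, 100 * x$upper)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from beta quantiles: for `k` successes in `n` trials
#' the lower bound is the `alpha/2` quantile of `Beta(k, n - k + 1)` (zero
#' when `k = 0`) and the upper bound the `1 - alpha/2` quantile of
#' `Beta(k + 1, n - k)` (one when `k = n`).
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n > 0`.
#' @param level confidence level (default 0.95).
#' @return A [proportion_ci()].
#' @examples
#' clopper_pearson(62, 86)   # 72.09% (61.38-81.23)
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n))
    stop("k and n must be single non-missing numbers")
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n with n > 0")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  proportion_ci(k / n, lower, upper, level, "clopper_pearson")
}

# plain Wald interval on the proportion scale, clipped to [0, 1]
wald_ci <- function(k, n, level = 0.95) {
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  proportion_ci(p, max(0, p - half), min(1, p + half), level, "wald")
}

#' Prevalence-adjusted logit confidence intervals for predictive values
#'
#' Confidence intervals for the positive and negative predictive value in
#' the style of Mercaldo, Lau and Zhou: the predictive values are written via
#' Bayes' theorem as functions of sensitivity, specificity and an assumed
#' prevalence, the interval is formed on the logit scale with a delta-method
#' variance built from the diseased and healthy sample sizes (prevalence held
#' fixed), and back-transformed. Because prevalence enters as a constant,
#' these intervals apply equally at the sample prevalence and at hypothetical
#' pre-test probabilities.
#'
#' When sensitivity or specificity sits on the boundary the logit variance is
#' undefined; with `adjusted = TRUE` the boundary proportion is replaced by
#' its Agresti-Coull-style adjusted value (`(k + z^2/2) / (n + z^2)`) before
#' transformation, otherwise an error is raised.
#'
#' @param se,sp sensitivity and specificity (proportions).
#' @param n_d,n_h diseased and healthy sample sizes behind `se` and `sp`.
#' @param prevalence assumed pre-test probability, strictly inside `(0, 1)`.
#' @param level confidence level.
#' @param adjusted use the boundary-adjusted variant (default `FALSE`).
#' @return A list with components `ppv` and `npv`, each a [proportion_ci()].
#' @examples
#' mercaldo_pv_ci(se = 62/86, sp = 498/906, n_d = 86, n_h = 906,
#'                prevalence = 86/992)
#' @export
mercaldo_pv_ci <- function(se, sp, n_d, n_h, prevalence, level = 0.95,
                           adjusted = FALSE) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (adjusted) {
    se <- (se * n_d + z^2 / 2) / (n_d + z^2)
    sp <- (sp * n_h + z^2 / 2) / (n_h + z^2)
  }
  if (se <= 0 || se >= 1 || sp <= 0 || sp >= 1)
    stop("se and sp must be strictly inside (0, 1); ",
         "use `adjusted = TRUE` for boundary values")
  pi <- prevalence
  ppv <- pi * se / (pi * se + (1 - pi) * (1 - sp))
  npv <- (1 - pi) * sp / ((1 - pi) * sp + pi * (1 - se))
  # delta-method variances of logit(PPV), logit(NPV) with pi fixed
  var_logit_ppv <- (1 - se) / (se * n_d) + sp / ((1 - sp) * n_h)
  var_logit_npv <- se / ((1 - se) * n_d) + (1 - sp) / (sp * n_h)
  back <- function(est, v) {
    lo <- stats::qlogis(est) - z * sqrt(v)
    hi <- stats::qlogis(est) + z * sqrt(v)
    proportion_ci(est, stats::plogis(lo), stats::plogis(hi), level, "mercaldo_logit")
  }
  list(ppv = back(ppv, var_logit_ppv), npv = back(npv, var_logit_npv))
}
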