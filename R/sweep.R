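#' Post-test probabilities at an assumed prevalence
#'
#' Bayes' theorem for a dichotomous test: the positive predictive value at
#' pre-test probability `prevalence` is
#' `pi*se / (pi*se + (1-pi)*(1-sp))` and the negative predictive value is
#' `(1-pi)*sp / ((1-pi)*sp + pi*(1-se))`. At a table's own prevalence these
#' agree exactly with the count-based `tp/(tp+fp)` and `tn/(tn+fn)`.
#' Degenerate denominators (e.g. `pi = 0` with `sp = 1`) return `NA`.
#'
#' @param se,sp sensitivity and specificity in `[0, 1]`.
#' @param prevalence pre-test probability (vectorized).
#' @return Numeric vector of post-test probabilities.
#' @examples
#' ppv_at(se = 58/86, sp = 526/906, prevalence = 0.20)  # 0.287
#' @export
ppv_at <- function(se, sp, prevalence) {
  num <- prevalence * se
  den <- num + (1 - prevalence) * (1 - sp)
  ifelse(den > 0, num / den, NA_real_)
}

#' @rdname ppv_at
#' @export
npv_at <- function(se, sp, prevalence) {
  num <- (1 - prevalence) * sp
  den <- num + prevalence * (1 - se)
  ifelse(den > 0, num / den, NA_real_)
}

#' Default pre-test probability grid
#'
#' The 18-point prevalence grid used for the post-test probability tables:
#' 2 to 40 percent with the sample prevalence 8.67 percent included.
#'
#' @return Numeric vector of proportions, strictly increasing.
#' @export
default_prevalence_grid <- function() {
  c(2, 4, 6, 8, 8.67, 10, 12, 14, 15, 16, 18, 20, 22, 24, 25, 26, 30, 40) / 100
}

#' Sweep post-test probabilities over a prevalence grid
#'
#' Evaluates PPV and NPV of one or more tests over a grid of pre-test
#' probabilities, with Mercaldo-style logit confidence intervals built from
#' fixed diseased/healthy sample sizes. Holding `n_d` and `n_h` fixed while
#' prevalence varies treats the sensitivity and specificity estimates (and
#' their sampling variances) as anchored in the observed sample and the
#' prevalence as a known external quantity; this is the bookkeeping used
#' when projecting a study's accuracy onto other populations, and is an
#' approximation at hypothetical prevalences.
#'
#' @param tests a data frame with columns `label`, `se`, `sp` (one row per
#'   test or combination rule), or a named list of `c(se, sp)` pairs.
#' @param grid prevalence values in `(0, 1)`, strictly increasing; default
#'   [default_prevalence_grid()].
#' @param n_d,n_h diseased and healthy sample sizes behind the accuracies.
#' @param level confidence level.
#' @return A data frame of class `prevalence_curve` in long format:
#'   `label`, `prevalence`, `ppv`, `ppv_lower`, `ppv_upper`, `npv`,
#'   `npv_lower`, `npv_upper`; attributes `n_d`, `n_h`, `level`, and a
#'   `tests` attribute recording the accuracies swept.
#' @examples
#' tests <- data.frame(label = c("LS-BMD", "TBS"),
#'                     se = c(58, 62) / 86, sp = c(526, 498) / 906)
#' cur <- prevalence_sweep(tests, n_d = 86, n_h = 906)
#' head(cur)
#' @export
prevalence_sweep <- function(tests, grid = default_prevalence_grid(),
                             n_d, n_h, level = 0.95) {
  if (is.list(tests) && !is.data.frame(tests)) {
    tests <- data.frame(label = names(tests),
                        se = vapply(tests, `[[`, 0, 1),
                        sp = vapply(tests, `[[`, 0, 2))
  }
  stopifnot(all(c("label", "se", "sp") %in% names(tests)))
  if (length(grid) == 0) stop("prevalence grid is empty")
  if (any(grid <= 0 | grid >= 1)) stop("grid values must lie strictly in (0, 1)")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  rows <- lapply(seq_len(nrow(tests)), function(i) {
    se <- tests$se[i]; sp <- tests$sp[i]
    cis <- lapply(grid, function(pi)
      mercaldo_pv_ci(se, sp, n_d, n_h, pi, level))
    data.frame(label = tests$label[i], prevalence = grid,
               ppv = ppv_at(se, sp, grid),
               ppv_lower = vapply(cis, function(ci) ci$ppv$lower, 0),
               ppv_upper = vapply(cis, function(ci) ci$ppv$upper, 0),
               npv = npv_at(se, sp, grid),
               npv_lower = vapply(cis, function(ci) ci$npv$lower, 0),
               npv_upper = vapply(cis, function(ci) ci$npv$upper, 0))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("prevalence_curve", "data.frame"),
            n_d = n_d, n_h = n_h, level = level,
            tests = tests[, c("label", "se", "sp")])
}

#' Linear regression of a post-test probability on prevalence
#'
#' Ordinary least squares of a test's PPV (or NPV) on pre-test prevalence
#' over the swept grid, both on the percentage scale. Reports the signed
#' Pearson correlation, its square, and the regression slope p-value. Over
#' a moderate prevalence range the Bayes curves are close to linear, so R
#' is near +1 for PPV and near -1 for NPV.
#'
#' @param curve a [prevalence_sweep()] result.
#' @param target `"ppv"` or `"npv"`.
#' @param label which test's curve to use; defaults to the only label
#'   present (an error if the curve holds several).
#' @return A list of class `sweep_regression`: `target`, `label`,
#'   `pearson_r`, `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
sweep_regression <- function(curve, target = c("ppv", "npv"), label = NULL) {
  stopifnot(inherits(curve, "prevalence_curve"))
  target <- match.arg(target)
  labs <- unique(curve$label)
  if (is.null(label)) {
    if (length(labs) > 1) stop("curve holds several tests; give `label`")
    label <- labs
  }
  sub <- curve[curve$label == label, ]
  if (nrow(sub) < 3) stop("need at least 3 grid points")
  y <- 100 * sub[[target]]
  xp <- 100 * sub$prevalence
  if (stats::sd(y) == 0)
    return(structure(list(target = target, label = label, pearson_r = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_,
                          slope = 0, intercept = y[1], n = length(y),
                          flags = "constant target"),
                     class = "sweep_regression"))
  fit <- stats::lm(y ~ xp)
  r <- stats::cor(xp, y)
  structure(list(target = target, label = label, pearson_r = r,
                 r_squared = r^2,
                 p_value = summary(fit)$coefficients[2, 4],
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(y), flags = character()),
            class = "sweep_regression")
}

#' @export
print.sweep_regression <- function(x, ...) {
  cat(sprintf("%s of %s vs prevalence: R = %.3f, R^2 = %.3f, p = %s\n",
              toupper(x$target), x$label, x$pearson_r, x$r_squared,
              format.pval(x$p_value, digits = 3, eps = 1e-6)))
  invisible(x)
}

#' Plot post-test probability curves
#'
#' Line chart of PPV or NPV against pre-test prevalence for every test in
#' the curve (base graphics).
#'
#' @param x a [prevalence_sweep()] result.
#' @param target `"ppv"` or `"npv"`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.prevalence_curve <- function(x, target = c("ppv", "npv"), ...) {
  target <- match.arg(target)
  labs <- unique(x$label)
  grid <- 100 * unique(x$prevalence)
  m <- sapply(labs, function(l) 100 * x[[target]][x$label == l])
  graphics::matplot(grid, m, type = "b", pch = seq_along(labs), lty = 1,
                    xlab = "Pre-test probability (%)",
                    ylab = paste0(toupper(target), " (%)"), ...)
  graphics::legend(if (target == "ppv") "topleft" else "bottomleft",
                   legend = labs, pch = seq_along(labs),
                   col = seq_along(labs), lty = 1, bty = "n")
  invisible(x)
}
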