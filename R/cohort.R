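#' Bivariate normal orthant probability
#'
#' `P(X <= a, Y <= b)` for standard bivariate normal `(X, Y)` with
#' correlation `rho`, by one-dimensional quadrature of
#' `phi(x) * Phi((b - rho x) / sqrt(1 - rho^2))` over `(-Inf, a]`.
#'
#' @param a,b upper limits on the standardized scale.
#' @param rho correlation in `(-1, 1)`.
#' @return The orthant probability.
#' @keywords internal
#' @export
bvn_orthant <- function(a, b, rho) {
  if (abs(rho) >= 1) stop("rho must lie strictly inside (-1, 1)")
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((b - rho * x) / s),
                   -Inf, a, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Parameters of the synthetic cohort generator
#'
#' Describes one disease group's (score A, score B) bivariate normal
#' distribution plus independent normal covariates. The defaults emulate a
#' postmenopausal referral cohort of 992 women (86 with a vertebral
#' fragility fracture): group-conditional means and SDs of the trabecular
#' bone score (unitless, test B) and lumbar-spine BMD (g/cm^2, test A), and
#' covariates age (years), height (cm), weight (kg), BMI and age at
#' menopause (years). The within-group dependence between the two scores is
#' a Gaussian-copula correlation `rho`; by default it is calibrated per
#' group with [calibrate_rho()] so that the expected both-positive cell at
#' the reference cutoffs (BMD 0.800 g/cm^2, TBS 1.204) matches the observed
#' joint-positive proportion (48.8 percent of fractured, 27.9 percent of
#' non-fractured women).
#'
#' @param n_fractured,n_nonfractured group sizes.
#' @param fractured,nonfractured named lists of `c(mean, sd)` per variable;
#'   must contain `tbs` and `ls_bmd`, may contain covariates.
#' @param rho length-2 numeric (fractured, non-fractured) copula
#'   correlation; `NULL` (default) calibrates each group to
#'   `joint_positive_target` at `cutoffs`.
#' @param cutoffs named vector `c(ls_bmd = , tbs = )` used for calibration.
#' @param joint_positive_target expected both-positive proportion per group
#'   (fractured, non-fractured) used when `rho` is `NULL`.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_fractured = 86, n_nonfractured = 906,
                          fractured = list(
                            age = c(69.6, 6.8), height_cm = c(158.1, 6.4),
                            weight_kg = c(62.6, 10.6), bmi = c(25.0, 4.1),
                            age_menopause = c(48.4, 5.5),
                            tbs = c(1.165, 0.095), ls_bmd = c(0.771, 0.127)),
                          nonfractured = list(
                            age = c(68.4, 6.8), height_cm = c(159.6, 6.1),
                            weight_kg = c(63.4, 10.4), bmi = c(24.8, 3.7),
                            age_menopause = c(49.5, 4.6),
                            tbs = c(1.214, 0.100), ls_bmd = c(0.828, 0.120)),
                          rho = NULL,
                          cutoffs = c(ls_bmd = 0.800, tbs = 1.204),
                          joint_positive_target = c(0.488, 0.279)) {
  stopifnot(n_fractured > 0, n_nonfractured > 0)
  for (g in list(fractured, nonfractured)) {
    if (!all(c("tbs", "ls_bmd") %in% names(g)))
      stop("each group needs `tbs` and `ls_bmd` (mean, sd) entries")
    sds <- vapply(g, `[[`, 0, 2)
    if (any(sds <= 0)) stop("all SDs must be positive")
  }
  if (is.null(rho)) {
    rho <- c(
      calibrate_rho(joint_positive_target[1], cutoffs[["ls_bmd"]], cutoffs[["tbs"]],
                    mean_a = fractured$ls_bmd[1], sd_a = fractured$ls_bmd[2],
                    mean_b = fractured$tbs[1], sd_b = fractured$tbs[2]),
      calibrate_rho(joint_positive_target[2], cutoffs[["ls_bmd"]], cutoffs[["tbs"]],
                    mean_a = nonfractured$ls_bmd[1], sd_a = nonfractured$ls_bmd[2],
                    mean_b = nonfractured$tbs[1], sd_b = nonfractured$tbs[2]))
  }
  if (length(rho) == 1) rho <- rep(rho, 2)
  if (any(abs(rho) >= 1)) stop("rho must lie strictly inside (-1, 1)")
  structure(list(n_fractured = n_fractured, n_nonfractured = n_nonfractured,
                 fractured = fractured, nonfractured = nonfractured,
                 rho = rho, cutoffs = cutoffs),
            class = "cohort_params")
}

#' Calibrate the copula correlation to a joint-positive proportion
#'
#' Root-finds the Gaussian-copula correlation `rho` such that the bivariate
#' normal probability of both scores falling at or below their cutoffs
#' equals `target`. The target must lie strictly between the Fréchet bounds
#' implied by the two marginal positive probabilities
#' (`max(0, pA + pB - 1)` and `min(pA, pB)`); outside them no correlation
#' can achieve it and the bounds are reported in the error.
#'
#' @param target desired both-positive probability.
#' @param cutoff_a,cutoff_b cutoffs on the two scores.
#' @param mean_a,sd_a,mean_b,sd_b marginal normal parameters.
#' @param tol root-finding tolerance on the probability scale.
#' @return The calibrated correlation (scalar).
#' @examples
#' calibrate_rho(0.279, 0.800, 1.204,
#'               mean_a = 0.828, sd_a = 0.120, mean_b = 1.214, sd_b = 0.100)
#' @export
calibrate_rho <- function(target, cutoff_a, cutoff_b,
                          mean_a, sd_a, mean_b, sd_b, tol = 1e-6) {
  za <- (cutoff_a - mean_a) / sd_a
  zb <- (cutoff_b - mean_b) / sd_b
  pa <- stats::pnorm(za); pb <- stats::pnorm(zb)
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  if (target <= lo + tol || target >= hi - tol)
    stop(sprintf(paste0("target %.4f not achievable by any correlation: ",
                        "Fréchet bounds are (%.4f, %.4f)"), target, lo, hi))
  f <- function(r) bvn_orthant(za, zb, r) - target
  stats::uniroot(f, lower = -1 + 1e-9, upper = 1 - 1e-9,
                 tol = 1e-12, f.lower = lo - target, f.upper = hi - target)$root
}

#' Generate a synthetic patient-level cohort
#'
#' Draws a cohort from the group-conditional model of [cohort_params()]:
#' within each disease group, (LS-BMD, TBS) come from a bivariate normal
#' with the group's means, SDs and copula correlation; covariates are
#' independent normals. The draw is deterministic given `seed`. Fractured
#' rows come first; `scale` multiplies both group sizes, which is useful for
#' convergence checks.
#'
#' @param params a [cohort_params()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param scale integer multiplier on both group sizes (default 1).
#' @return A data frame with columns `id`, the covariates present in the
#'   parameters, `tbs`, `ls_bmd` and `fracture` (1 = fractured). The seed
#'   and correlations used are attached as attributes.
#' @export
generate_cohort <- function(params = cohort_params(), seed = NULL, scale = 1) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  draw_group <- function(g, n, rho, fracture) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    out <- list()
    for (v in setdiff(names(g), c("tbs", "ls_bmd")))
      out[[v]] <- g[[v]][1] + g[[v]][2] * stats::rnorm(n)
    out$tbs <- g$tbs[1] + g$tbs[2] * z2
    out$ls_bmd <- g$ls_bmd[1] + g$ls_bmd[2] * z1
    out$fracture <- rep(fracture, n)
    as.data.frame(out)
  }
  nf <- params$n_fractured * scale
  nh <- params$n_nonfractured * scale
  cohort <- rbind(draw_group(params$fractured, nf, params$rho[1], 1L),
                  draw_group(params$nonfractured, nh, params$rho[2], 0L))
  cohort <- cbind(id = seq_len(nrow(cohort)), cohort)
  attr(cohort, "seed") <- seed
  attr(cohort, "rho") <- params$rho
  cohort
}

#' Add a T-score column to a cohort
#'
#' Standardizes `ls_bmd` against a young-adult reference mean and SD:
#' `(ls_bmd - mu_ref) / sigma_ref`. No manufacturer reference is assumed;
#' both values must be supplied.
#'
#' @param cohort a cohort data frame with an `ls_bmd` column.
#' @param mu_ref,sigma_ref reference mean and SD (g/cm^2).
#' @return The cohort with an added `ls_bmd_t_score` column.
#' @export
add_t_score <- function(cohort, mu_ref, sigma_ref) {
  stopifnot(sigma_ref > 0, "ls_bmd" %in% names(cohort))
  cohort$ls_bmd_t_score <- (cohort$ls_bmd - mu_ref) / sigma_ref
  cohort
}

#' Baseline comparison of fractured vs non-fractured groups
#'
#' For each continuous variable in the cohort: group means and SDs, a
#' two-sample t-test (pooled variance when Levene's test at the 0.05 level
#' accepts homogeneity, Welch otherwise) and Levene's test of homogeneity of
#' variance centred at the group means. A zero-variance variable is flagged
#' rather than fatal.
#'
#' @param cohort a cohort data frame with a 0/1 `fracture` column.
#' @param vars variables to compare; default all numeric columns except
#'   `id` and `fracture`.
#' @return A data frame of class `baseline_comparison` with one row per
#'   variable: group means/SDs, pooled mean/SD, `t`, `t_p`, `levene_F`,
#'   `levene_p`, `t_variant`, `flag`.
#' @export
baseline_comparison <- function(cohort, vars = NULL) {
  if (!"fracture" %in% names(cohort)) stop("cohort lacks `fracture`")
  g <- factor(cohort$fracture, levels = c(1, 0),
              labels = c("fractured", "nonfractured"))
  if (any(table(g) < 2)) stop("need at least 2 rows in each group")
  if (is.null(vars))
    vars <- setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)],
                    c("id", "fracture"))
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    m <- tapply(x, g, mean); s <- tapply(x, g, stats::sd)
    base <- data.frame(variable = v,
                       mean_fractured = m[["fractured"]], sd_fractured = s[["fractured"]],
                       mean_nonfractured = m[["nonfractured"]], sd_nonfractured = s[["nonfractured"]],
                       mean_pooled = mean(x), sd_pooled = stats::sd(x))
    if (any(s == 0, na.rm = TRUE) || stats::sd(x) == 0) {
      return(cbind(base, t = NA, t_p = NA, levene_F = NA, levene_p = NA,
                   t_variant = NA, flag = "zero variance"))
    }
    lev <- car::leveneTest(x ~ g, center = mean)
    equal_var <- lev[1, "Pr(>F)"] >= 0.05
    tt <- stats::t.test(x ~ g, var.equal = equal_var)
    cbind(base, t = unname(tt$statistic), t_p = tt$p.value,
          levene_F = lev[1, "F value"], levene_p = lev[1, "Pr(>F)"],
          t_variant = if (equal_var) "pooled" else "welch", flag = "")
  })
  structure(do.call(rbind, rows),
            class = c("baseline_comparison", "data.frame"))
}

#' Two-sample t-test from summary statistics
#'
#' Pooled or Welch t-test computed from group means, SDs and sizes only —
#' for checking printed baseline tables when patient-level data are not
#' available.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param var_equal pooled-variance test if `TRUE`, Welch otherwise.
#' @return List with `t`, `df`, `p_value`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = FALSE) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 > 1, n2 > 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}
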