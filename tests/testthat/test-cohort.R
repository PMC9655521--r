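test_that("generator is deterministic and honours its parameters", {
  par <- cohort_params(rho = c(0.6, 0.55))
  a <- generate_cohort(par, seed = 5)
  b <- generate_cohort(par, seed = 5)
  expect_identical(a, b)
  expect_identical(nrow(a), 992L)
  expect_identical(sum(a$fracture), 86L)
  # byte-identical CSV output under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort_csv(a, f1, "seed 5")
  write_cohort_csv(b, f2, "seed 5")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  c_ <- generate_cohort(par, seed = 6)
  expect_false(identical(a$tbs, c_$tbs))
})

test_that("sample moments converge to the group parameters", {
  par <- cohort_params(rho = c(0.6, 0.55))
  coh <- generate_cohort(par, seed = 31, scale = 100)
  frac <- coh[coh$fracture == 1, ]
  non <- coh[coh$fracture == 0, ]
  within3se <- function(x, mean, sd) abs(mean(x) - mean) < 3 * sd / sqrt(length(x))
  expect_true(within3se(frac$tbs, 1.165, 0.095))
  expect_true(within3se(frac$ls_bmd, 0.771, 0.127))
  expect_true(within3se(non$tbs, 1.214, 0.100))
  expect_true(within3se(non$ls_bmd, 0.828, 0.120))
  expect_true(within3se(non$age, 68.4, 6.8))
  # within-group correlation near the requested copula value
  expect_lt(abs(cor(frac$tbs, frac$ls_bmd) - 0.6), 3 / sqrt(nrow(frac)))
  # zero correlation when requested
  ind <- generate_cohort(cohort_params(rho = 0), seed = 9, scale = 10)
  indn <- ind[ind$fracture == 0, ]
  expect_lt(abs(cor(indn$tbs, indn$ls_bmd)), 3 / sqrt(nrow(indn)))
})

test_that("orthant probability quadrature agrees with closed forms and simulation", {
  # independence factorizes
  expect_equal(bvn_orthant(0.3, -0.5, 0), pnorm(0.3) * pnorm(-0.5),
               tolerance = 1e-12)
  # symmetric quadrant at rho = 0.5 has the known closed form 1/3
  expect_equal(bvn_orthant(0, 0, 0.5), 1 / 3, tolerance = 1e-8)
  set.seed(23)
  z1 <- rnorm(1e6); z2 <- 0.7 * z1 + sqrt(1 - 0.49) * rnorm(1e6)
  mc <- mean(z1 <= 0.4 & z2 <= -0.2)
  expect_lt(abs(bvn_orthant(0.4, -0.2, 0.7) - mc), 3 * sqrt(mc * (1 - mc) / 1e6))
})

test_that("rho calibration hits its target and respects the Frechet bounds", {
  target <- 0.279
  rho <- calibrate_rho(target, 0.800, 1.204,
                       mean_a = 0.828, sd_a = 0.120,
                       mean_b = 1.214, sd_b = 0.100)
  za <- (0.800 - 0.828) / 0.120; zb <- (1.204 - 1.214) / 0.100
  expect_equal(bvn_orthant(za, zb, rho), target, tolerance = 1e-6)
  # Monte-Carlo oracle: simulated orthant mass at the calibrated rho
  set.seed(41)
  z1 <- rnorm(1e6); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1e6)
  expect_lt(abs(mean(z1 <= za & z2 <= zb) - target), 0.002)
  # independence target recovers rho ~ 0
  rho0 <- calibrate_rho(pnorm(za) * pnorm(zb), 0.800, 1.204,
                        0.828, 0.120, 1.214, 0.100)
  expect_lt(abs(rho0), 1e-6)
  # monotone: larger joint-positive target needs larger rho
  rho_hi <- calibrate_rho(0.35, 0.800, 1.204, 0.828, 0.120, 1.214, 0.100)
  expect_gt(rho_hi, rho)
  # outside the Frechet bounds is rejected with the bounds in the message
  expect_error(calibrate_rho(0.41, 0.800, 1.204, 0.828, 0.120, 1.214, 0.100),
               "bounds")
  # below the lower Frechet bound (both marginals near 1)
  expect_error(calibrate_rho(0.10, 0.800, 1.204, 0.500, 0.100, 1.000, 0.100),
               "bounds")
})

test_that("defaults calibrate each disease group to its joint-positive cell", {
  par <- study_params()
  expect_length(par$rho, 2)
  expect_true(all(par$rho > 0 & par$rho < 1))
  za <- (0.800 - 0.771) / 0.127; zb <- (1.204 - 1.165) / 0.095
  expect_equal(bvn_orthant(za, zb, par$rho[1]), 0.488, tolerance = 1e-6)
  za2 <- (0.800 - 0.828) / 0.120; zb2 <- (1.204 - 1.214) / 0.100
  expect_equal(bvn_orthant(za2, zb2, par$rho[2]), 0.279, tolerance = 1e-6)
})

test_that("dichotomized synthetic cohorts recover the reference cell structure", {
  # whole-cohort cell proportions within 2 points of the reference
  # concordance table at 100x the study size; the empirical OR-rule
  # sensitivity agrees with the generator's own analytic orthant value
  par <- study_params()
  coh <- generate_cohort(par, seed = 99, scale = 100)
  xt <- dichotomize(coh, 0.800, 1.204)
  obs <- c(xt$diseased, xt$healthy) / nrow(coh)
  ref <- c(42, 16, 20, 8, 253, 127, 155, 371) / 992
  expect_lt(max(abs(obs - ref)), 0.02)
  emp_se_or <- 1 - xt$diseased[["nn"]] / sum(xt$diseased)
  za <- (0.800 - par$fractured$ls_bmd[1]) / par$fractured$ls_bmd[2]
  zb <- (1.204 - par$fractured$tbs[1]) / par$fractured$tbs[2]
  analytic_se_or <- pnorm(za) + pnorm(zb) - bvn_orthant(za, zb, par$rho[1])
  expect_lt(abs(emp_se_or - analytic_se_or), 0.03)
  # large-n crosstab cell fractions track the printed per-group percentages
  # up to the documented Gaussian-marginal misfit (largest in the fractured
  # both-negative cell); the healthy group is reproduced within ~1.5 points
  pct <- crosstab_percent(xt, digits = NULL)
  expect_lt(max(abs(pct$healthy - c(27.9, 14.0, 17.1, 41.0))), 1.5)
})

test_that("baseline comparison flags group differences the design implies", {
  par <- study_params()
  coh <- generate_cohort(par, seed = 77, scale = 10)
  bc <- baseline_comparison(coh)
  expect_s3_class(bc, "baseline_comparison")
  tbs_row <- bc[bc$variable == "tbs", ]
  expect_lt(tbs_row$t_p, 0.001)
  bmd_row <- bc[bc$variable == "ls_bmd", ]
  expect_lt(bmd_row$t_p, 0.001)
  # pooled mean sits between the group means
  for (i in seq_len(nrow(bc))) {
    rng <- range(bc$mean_fractured[i], bc$mean_nonfractured[i])
    expect_gte(bc$mean_pooled[i], rng[1])
    expect_lte(bc$mean_pooled[i], rng[2])
  }
  # identical groups give t ~ 0
  same <- coh
  same$tbs <- rep(seq(1, 1.4, length.out = 496), 20)[seq_len(nrow(same))]
  set.seed(1); same$tbs <- sample(same$tbs)
  bc2 <- baseline_comparison(same, vars = "tbs")
  expect_lt(abs(bc2$t), 2.5)
  # zero-variance variable flagged, not fatal
  same$flat <- 1
  bc3 <- baseline_comparison(same, vars = c("tbs", "flat"))
  expect_identical(bc3$flag[bc3$variable == "flat"], "zero variance")
})

test_that("summary-statistics t-test reproduces the printed baseline verdicts", {
  # group means/SDs of the two bone scores imply p < 0.01
  tbs <- t_test_summary(1.165, 0.095, 86, 1.214, 0.100, 906)
  expect_lt(tbs$p_value, 0.01)
  bmd <- t_test_summary(0.771, 0.127, 86, 0.828, 0.120, 906)
  expect_lt(bmd$p_value, 0.01)
  # agrees with t.test on raw data
  set.seed(2)
  x <- rnorm(30); y <- rnorm(40, 0.5)
  ours <- t_test_summary(mean(x), sd(x), 30, mean(y), sd(y), 40)
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  pooled <- t_test_summary(mean(x), sd(x), 30, mean(y), sd(y), 40, var_equal = TRUE)
  refp <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$p_value, refp$p.value, tolerance = 1e-10)
})

test_that("t-score standardization and parameter validation", {
  coh <- data.frame(ls_bmd = c(0.800, 0.950))
  out <- add_t_score(coh, mu_ref = 1.047, sigma_ref = 0.107)
  # the reference checkpoint: 0.800 g/cm2 corresponds to roughly T = -2.3
  expect_equal(out$ls_bmd_t_score[1], -2.3, tolerance = 0.02)
  expect_error(cohort_params(n_fractured = 0), "n_fractured")
  bad <- list(tbs = c(1.2, 0), ls_bmd = c(0.8, 0.1))
  expect_error(cohort_params(fractured = bad, rho = 0.5), "SD")
})
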