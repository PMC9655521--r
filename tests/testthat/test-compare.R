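test_that("McNemar chi-square on discordant cells matches the closed form", {
  xt <- study_xt()
  se_cmp <- mcnemar_paired(xt, "se")
  expect_equal(se_cmp$statistic, (20 - 16)^2 / 36, tolerance = 1e-12)
  expect_equal(round(se_cmp$p_value, 3), 0.505)
  sp_cmp <- mcnemar_paired(xt, "sp")
  expect_equal(sp_cmp$statistic, (155 - 127)^2 / 282, tolerance = 1e-12)
  expect_equal(round(sp_cmp$statistic, 2), 2.78)
})

test_that("McNemar statistic is symmetric in the test labels and handles b = c", {
  set.seed(13)
  for (i in 1:20) {
    xt <- random_xt()
    swapped <- paired_crosstab(
      xt$diseased[c("pp", "np", "pn", "nn")] |> setNames(c("pp", "pn", "np", "nn")),
      xt$healthy[c("pp", "np", "pn", "nn")] |> setNames(c("pp", "pn", "np", "nn")))
    for (target in c("se", "sp"))
      expect_equal(mcnemar_paired(xt, target)$statistic,
                   mcnemar_paired(swapped, target)$statistic, tolerance = 1e-12)
  }
  balanced <- paired_crosstab(c(pp = 10, pn = 7, np = 7, nn = 6),
                              c(pp = 5, pn = 5, np = 5, nn = 5))
  cmp <- mcnemar_paired(balanced, "se")
  expect_identical(cmp$statistic, 0)
  expect_identical(cmp$p_value, 1)
  none <- paired_crosstab(c(pp = 10, pn = 0, np = 0, nn = 6),
                          c(pp = 5, pn = 5, np = 5, nn = 5))
  cmp0 <- mcnemar_paired(none, "se")
  expect_identical(cmp0$statistic, 0)
  expect_match(cmp0$flags, "no discordance")
})

test_that("weighted generalized score test behaves on reference and degenerate data", {
  xt <- study_xt()
  ppv <- wgs_test(xt, "ppv")
  expect_lt(ppv$statistic, 0.01)        # reference comparison is far from significant
  expect_gt(ppv$p_value, 0.9)
  npv <- wgs_test(xt, "npv")
  expect_gt(npv$statistic, 0.1)         # same order as the published statistic
  expect_lt(npv$statistic, 0.25)
  expect_gt(npv$p_value, 0.05)
  # identical tests give exactly zero
  dup <- paired_crosstab(c(pp = 30, pn = 0, np = 0, nn = 20),
                         c(pp = 40, pn = 0, np = 0, nn = 160))
  expect_equal(wgs_test(dup, "ppv")$statistic, 0, tolerance = 1e-12)
  # label-swap invariance
  swapped <- paired_crosstab(
    xt$diseased[c("pp", "np", "pn", "nn")] |> setNames(c("pp", "pn", "np", "nn")),
    xt$healthy[c("pp", "np", "pn", "nn")] |> setNames(c("pp", "pn", "np", "nn")))
  for (target in c("ppv", "npv"))
    expect_equal(wgs_test(xt, target)$statistic,
                 wgs_test(swapped, target)$statistic, tolerance = 1e-12)
  # the two variance variants agree closely on well-filled tables
  expect_equal(wgs_test(xt, "npv", "weighted")$statistic,
               wgs_test(xt, "npv", "unweighted")$statistic, tolerance = 1e-2)
  # no positive calls at all for one test
  nopos <- paired_crosstab(c(pp = 0, pn = 0, np = 10, nn = 10),
                           c(pp = 0, pn = 0, np = 10, nn = 80))
  expect_error(wgs_test(nopos, "ppv"), "no positive")
})

test_that("WGS test holds its size under the null", {
  # equal-accuracy, conditionally dependent paired tests; n = 500 at 30%
  # prevalence; empirical rejection at nominal 5% must stay below 7%
  set.seed(11)
  nsim <- 2000
  pd <- c(0.55, 0.15, 0.15, 0.15)
  ph <- c(0.10, 0.10, 0.10, 0.70)
  dm <- stats::rmultinom(nsim, 150, pd)
  hm <- stats::rmultinom(nsim, 350, ph)
  rej <- logical(nsim)
  for (i in seq_len(nsim)) {
    xt <- paired_crosstab(setNames(dm[, i], c("pp", "pn", "np", "nn")),
                          setNames(hm[, i], c("pp", "pn", "np", "nn")))
    rej[i] <- wgs_test(xt, "ppv")$p_value < 0.05
  }
  expect_lte(mean(rej), 0.07)
})

test_that("log odds ratio Z-test matches hand computation and the reference verdicts", {
  t1 <- binary_test_table(200, 100, 50, 100, label = "t1")  # OR = 4
  t2 <- binary_test_table(100, 100, 100, 100, label = "t2") # OR = 1
  z <- z_test_log_or(t1, t2)
  v1 <- 1 / 200 + 1 / 100 + 1 / 50 + 1 / 100
  v2 <- 4 / 100
  expect_equal(z$statistic, log(4) / sqrt(v1 + v2), tolerance = 1e-12)
  expect_equal(z$p_value, 2 * pnorm(-abs(z$statistic)), tolerance = 1e-12)
  # identical tables
  same <- z_test_log_or(t1, t1)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  # OR-rule vs LS-BMD on the reference data: borderline, not significant
  xt <- study_xt()
  zref <- z_test_log_or(combine_tests(xt, "or"), marginal_table(xt, "a"))
  expect_gt(zref$p_value, 0.05)
  expect_lt(zref$p_value, 0.10)
  # zero-cell policy
  zc <- binary_test_table(5, 0, 5, 5)
  expect_error(z_test_log_or(zc, t1), "zero cell")
  expect_no_error(z_test_log_or(zc, t1, correction = TRUE))
})

test_that("Cohen's kappa matches the reference values and an independent oracle", {
  xt <- study_xt()
  expect_equal(round(cohens_kappa(xt, "all")$kappa, 3), 0.355)
  expect_equal(round(cohens_kappa(xt, "healthy")$kappa, 3), 0.367)
  expect_equal(round(cohens_kappa(xt, "diseased")$kappa, 3), 0.010)
  # perfect agreement
  agree <- paired_crosstab(c(pp = 10, pn = 0, np = 0, nn = 5),
                           c(pp = 20, pn = 0, np = 0, nn = 30))
  expect_equal(cohens_kappa(agree)$kappa, 1)
  # both tests constant
  const <- paired_crosstab(c(pp = 10, pn = 0, np = 0, nn = 0),
                           c(pp = 20, pn = 0, np = 0, nn = 0))
  expect_true(is.na(cohens_kappa(const)$kappa))
  skip_if_not_installed("e1071")
  set.seed(21)
  for (i in 1:20) {
    xt <- random_xt()
    cells <- xt$diseased + xt$healthy
    m <- matrix(cells[c("pp", "pn", "np", "nn")], 2, byrow = TRUE)
    expect_equal(cohens_kappa(xt, "all")$kappa,
                 e1071::classAgreement(m)$kappa, tolerance = 1e-10)
  }
})

test_that("pooled kappa from counts equals kappa from agreement proportions", {
  xt <- study_xt()
  k <- cohens_kappa(xt, "all")
  # recompute from the published pooled agreement percentages (one decimal);
  # the two routes agree up to the percentage print rounding
  pct <- c(pp = 29.8, pn = 14.4, np = 17.6, nn = 38.2) / 100
  p_o <- pct[["pp"]] + pct[["nn"]]
  pa <- pct[["pp"]] + pct[["pn"]]; pb <- pct[["pp"]] + pct[["np"]]
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  expect_lt(abs(k$kappa - (p_o - p_e) / (1 - p_e)), 0.002)
})

test_that("Bonferroni adjustment is min(1, p*m) and order-preserving", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04), 2), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.9, 3), 1)
  set.seed(3)
  p <- runif(20)
  m <- 25
  expect_equal(bonferroni_adjust(p, m), pmin(1, p * m))
  expect_false(is.unsorted(bonferroni_adjust(sort(p), m)))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(runif(5), 3), "family size")
})

test_that("the comparison battery is assembled with adjusted p-values", {
  cmp <- compare_tests(study_xt())
  expect_identical(nrow(cmp), 8L)
  expect_true(all(cmp$p_adjusted >= cmp$p_value))
  expect_true(all(cmp$p_adjusted <= 1))
  # on the reference data every member of the family is non-significant
  expect_true(all(cmp$verdict_at_0.05 == "ns"))
})
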