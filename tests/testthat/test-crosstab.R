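test_that("largest-remainder reconstruction recovers the reference counts exactly", {
  xt <- crosstab_from_percent(c(48.8, 18.6, 23.3, 9.3), c(27.9, 14.0, 17.1, 41.0),
                              n_diseased = 86, n_healthy = 906)
  expect_identical(unname(xt$diseased), c(42L, 16L, 20L, 8L))
  expect_identical(unname(xt$healthy), c(253L, 127L, 155L, 371L))
  expect_identical(sum(xt$diseased), 86L)
  expect_identical(sum(xt$healthy), 906L)
  # round-trip: recomputed cell percentages round back to the printed values;
  # the one exception is the non-fractured both-negative cell, printed as
  # 41.0 where 371/906 regenerates 40.9 (publication print rounding)
  pct <- crosstab_percent(xt, digits = 1)
  expect_equal(unname(pct$diseased), c(48.8, 18.6, 23.3, 9.3))
  expect_equal(unname(pct$healthy), c(27.9, 14.0, 17.1, 40.9))
  expect_lt(max(abs(pct$healthy - c(27.9, 14.0, 17.1, 41.0))), 0.11)
})

test_that("reconstruction handles degenerate and invalid input", {
  xt <- crosstab_from_percent(c(100, 0, 0, 0), c(100, 0, 0, 0), 50, 10)
  expect_identical(unname(xt$diseased), c(50L, 0L, 0L, 0L))
  expect_error(crosstab_from_percent(c(50, 30, 10, 5), c(25, 25, 25, 25), 10, 10),
               "diseased")
  expect_error(crosstab_from_percent(c(50, 30, 30, -10), c(25, 25, 25, 25), 10, 10),
               "negative")
  expect_error(crosstab_from_percent(c(25, 25, 25, 25), c(25, 25, 25, 25), 0, 10),
               "positive")
})

test_that("largest-remainder rounding satisfies its defining properties", {
  set.seed(31)
  for (i in 1:200) {
    raw <- runif(4)
    pct <- 100 * raw / sum(raw)
    total <- sample(10:2000, 1)
    xt <- crosstab_from_percent(pct, c(25, 25, 25, 25), total, 100)
    counts <- as.numeric(xt$diseased)
    exact <- pct / 100 * total
    expect_identical(sum(counts), as.numeric(total))
    # every count is the floor or the ceiling of its exact value
    expect_true(all(counts == floor(exact) | counts == ceiling(exact)))
    # cells rounded up carry remainders >= those of cells rounded down
    up <- counts > floor(exact)
    rem <- exact - floor(exact)
    if (any(up) && any(!up))
      expect_gte(min(rem[up]), max(rem[!up]) - 1e-9)
  }
})

test_that("marginal tables collapse correctly and preserve totals", {
  xt <- study_xt()
  tb <- marginal_table(xt, "b")  # TBS
  expect_equal(c(tb$tp, tb$fp, tb$fn, tb$tn), c(62L, 408L, 24L, 498L))
  ta <- marginal_table(xt, "a")  # LS-BMD
  expect_equal(c(ta$tp, ta$fp, ta$fn, ta$tn), c(58L, 380L, 28L, 526L))
  expect_identical(ta$tp + ta$fn + ta$fp + ta$tn, 992L)
  zero <- paired_crosstab(c(pp = 0, pn = 0, np = 0, nn = 0),
                          c(pp = 0, pn = 0, np = 0, nn = 0))
  mz <- marginal_table(zero, "a")
  expect_identical(c(mz$tp, mz$fp, mz$fn, mz$tn), c(0L, 0L, 0L, 0L))
})

test_that("crosstab constructor validates counts", {
  expect_error(paired_crosstab(c(pp = -1, pn = 0, np = 0, nn = 0),
                               c(pp = 1, pn = 1, np = 1, nn = 1)), "non-negative")
  expect_error(paired_crosstab(c(1, 2, 3), c(1, 2, 3, 4)), "4 counts")
  expect_error(paired_crosstab(c(pp = 1.5, pn = 0, np = 0, nn = 0),
                               c(pp = 1, pn = 1, np = 1, nn = 1)), "integers")
})

test_that("dichotomize uses score-at-or-below-cutoff positivity", {
  one <- data.frame(ls_bmd = 0.9, tbs = 1.204, fracture = 1)
  xt <- dichotomize(one, 0.800, 1.204)
  expect_identical(xt$diseased[["np"]], 1L)  # BMD negative, TBS positive (equal)
  just_above <- data.frame(ls_bmd = 0.9, tbs = 1.2041, fracture = 1)
  xt2 <- dichotomize(just_above, 0.800, 1.204)
  expect_identical(xt2$diseased[["nn"]], 1L)  # strictly above cutoff is negative
})

test_that("dichotomize drops incomplete rows with a message and rejects empty input", {
  d <- data.frame(ls_bmd = c(0.7, NA, 0.9), tbs = c(1.1, 1.2, 1.3),
                  fracture = c(1, 0, 0))
  expect_message(xt <- dichotomize(d, 0.800, 1.204), "dropped 1")
  expect_identical(sum(xt$diseased) + sum(xt$healthy), 2L)
  empty <- data.frame(ls_bmd = NA_real_, tbs = 1.2, fracture = 1)
  expect_error(suppressMessages(dichotomize(empty, 0.8, 1.2)), "no complete rows")
  bad <- data.frame(ls_bmd = 0.7, tbs = 1.1, fracture = 2)
  expect_error(dichotomize(bad, 0.8, 1.2), "0/1")
})

test_that("dichotomizing a manual cohort reproduces a hand tally", {
  set.seed(12)
  n <- 500
  coh <- data.frame(ls_bmd = runif(n, 0.5, 1.1), tbs = runif(n, 0.9, 1.5),
                    fracture = rbinom(n, 1, 0.2))
  xt <- dichotomize(coh, 0.800, 1.204)
  pa <- coh$ls_bmd <= 0.800; pb <- coh$tbs <= 1.204
  expect_identical(xt$diseased[["pp"]], sum(pa & pb & coh$fracture == 1))
  expect_identical(xt$healthy[["nn"]], sum(!pa & !pb & coh$fracture == 0))
})

test_that("crosstab JSON round-trips in both count and percent form", {
  xt <- study_xt()
  path <- tempfile(fileext = ".json")
  write_crosstab_json(xt, path)
  back <- read_crosstab_json(path)
  expect_identical(back$diseased, xt$diseased)
  expect_identical(back$healthy, xt$healthy)
  expect_identical(back$test_a, "LS-BMD")
  # percent + totals form
  pfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    test_a = "LS-BMD", test_b = "TBS",
    percent = list(diseased = list(pp = 48.8, pn = 18.6, np = 23.3, nn = 9.3),
                   healthy = list(pp = 27.9, pn = 14.0, np = 17.1, nn = 41.0)),
    totals = list(diseased = 86, healthy = 906)), pfile, auto_unbox = TRUE)
  back2 <- read_crosstab_json(pfile)
  expect_identical(back2$diseased, xt$diseased)
  expect_error(read_crosstab_json({
    f <- tempfile(); jsonlite::write_json(list(test_a = "x"), f); f
  }), "diseased")
})

test_that("cohort CSV round-trips and validates required columns", {
  coh <- generate_cohort(cohort_params(n_fractured = 5, n_nonfractured = 10),
                         seed = 3)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, path, header_comment = "seed 3")
  back <- read_cohort_csv(path)
  expect_equal(back$tbs, coh$tbs, tolerance = 1e-12)
  expect_equal(back$fracture, coh$fracture)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_cohort_csv(bad), "tbs")
})
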