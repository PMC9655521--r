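#' Paired cross-classification of two dichotomous tests by disease status
#'
#' The central data structure of the package: the 2 x 2 x 2 table obtained by
#' cross-classifying every subject by the result (positive/negative) of two
#' dichotomous diagnostic tests and by disease status. All empirical
#' statistics in the package (accuracy panels, combination rules, subgroup
#' analyses, agreement and paired comparisons) are functions of these eight
#' counts.
#'
#' Cell naming: the first subscript letter refers to test A, the second to
#' test B, so `pn` counts subjects positive on test A and negative on test B.
#' In the motivating bone-densitometry application test A is lumbar-spine BMD
#' and test B is the trabecular bone score.
#'
#' @param diseased,healthy numeric vectors of four non-negative integer
#'   counts, named or in the order `pp`, `pn`, `np`, `nn`.
#' @param test_a,test_b display names of the two tests.
#' @return An object of class `paired_crosstab`: a list with components
#'   `diseased` and `healthy` (named integer vectors of length 4) and the two
#'   test labels.
#' @examples
#' xt <- paired_crosstab(diseased = c(pp = 42, pn = 16, np = 20, nn = 8),
#'                       healthy  = c(pp = 253, pn = 127, np = 155, nn = 371),
#'                       test_a = "LS-BMD", test_b = "TBS")
#' xt
#' marginal_table(xt, "b")
#' @seealso [crosstab_from_percent()], [marginal_table()], [dichotomize()],
#'   [paired_dta()]
#' @export
paired_crosstab <- function(diseased, healthy, test_a = "test A", test_b = "test B") {
  diseased <- check_cells(diseased, "diseased")
  healthy <- check_cells(healthy, "healthy")
  structure(list(diseased = diseased, healthy = healthy,
                 test_a = test_a, test_b = test_b),
            class = "paired_crosstab")
}

cell_names <- c("pp", "pn", "np", "nn")

check_cells <- function(x, group) {
  if (length(x) != 4L)
    stop("`", group, "` must contain exactly 4 counts (pp, pn, np, nn)")
  if (is.null(names(x))) names(x) <- cell_names
  x <- x[cell_names]
  if (anyNA(x)) stop("`", group, "` counts must be named pp, pn, np, nn")
  if (any(x < 0)) stop("`", group, "` counts must be non-negative")
  if (any(abs(x - round(x)) > 1e-8)) stop("`", group, "` counts must be integers")
  storage.mode(x) <- "integer"
  x
}

#' @export
print.paired_crosstab <- function(x, ...) {
  cat("Paired cross-classification:", x$test_a, "x", x$test_b, "\n")
  nd <- sum(x$diseased); nh <- sum(x$healthy)
  m <- rbind(x$diseased, x$healthy)
  dimnames(m) <- list(c(sprintf("diseased (n=%d)", nd), sprintf("healthy (n=%d)", nh)),
                      c("A+B+", "A+B-", "A-B+", "A-B-"))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.paired_crosstab <- function(x, ...) {
  data.frame(group = rep(c("diseased", "healthy"), each = 4L),
             test_a = rep(c("positive", "positive", "negative", "negative"), 2L),
             test_b = rep(c("positive", "negative", "positive", "negative"), 2L),
             count = c(x$diseased, x$healthy))
}

n_diseased <- function(x) sum(x$diseased)
n_healthy <- function(x) sum(x$healthy)

#' Reconstruct integer counts from printed cell percentages
#'
#' Recovers the eight counts of a [paired_crosstab()] from the cell
#' percentages of a printed concordance table together with the two group
#' totals, using largest-remainder rounding constrained so that each group's
#' four counts sum exactly to its total. With percentages printed to one
#' decimal this reconstruction is exact: re-expressing the recovered counts
#' as percentages and rounding to one decimal returns the printed values.
#'
#' @param pct_diseased,pct_healthy numeric vectors of four cell percentages
#'   (in percent, summing to 100 up to printing tolerance), named or ordered
#'   `pp`, `pn`, `np`, `nn`.
#' @param n_diseased,n_healthy positive integer group totals.
#' @param tol maximum allowed deviation of each group's percentage sum from
#'   100 (default 0.2, the worst case for four values rounded to one decimal).
#' @inheritParams paired_crosstab
#' @return A [paired_crosstab()].
#' @examples
#' crosstab_from_percent(c(48.8, 18.6, 23.3, 9.3), c(27.9, 14.0, 17.1, 41.0),
#'                       n_diseased = 86, n_healthy = 906)
#' @export
crosstab_from_percent <- function(pct_diseased, pct_healthy,
                                  n_diseased, n_healthy,
                                  test_a = "test A", test_b = "test B",
                                  tol = 0.2) {
  if (n_diseased <= 0 || n_healthy <= 0) stop("group totals must be positive")
  d <- largest_remainder(pct_diseased, n_diseased, "diseased", tol)
  h <- largest_remainder(pct_healthy, n_healthy, "healthy", tol)
  paired_crosstab(d, h, test_a = test_a, test_b = test_b)
}

largest_remainder <- function(pct, total, group, tol) {
  if (length(pct) != 4L) stop("`pct_", group, "` must have 4 cells")
  if (any(pct < 0)) stop("negative percentage in the ", group, " group")
  s <- sum(pct)
  if (abs(s - 100) > tol)
    stop("percentages for the ", group, " group sum to ", format(s),
         ", outside 100 +/- ", tol)
  raw <- pct / s * total
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), cell_names)
}

#' Cell percentages of a paired crosstab
#'
#' Inverse of [crosstab_from_percent()]: expresses each group's four cells as
#' percentages of the group total.
#'
#' @param x a [paired_crosstab()].
#' @param digits rounding for the returned percentages; `NULL` for full
#'   precision.
#' @return A list with components `diseased` and `healthy`.
#' @export
crosstab_percent <- function(x, digits = 1) {
  stopifnot(inherits(x, "paired_crosstab"))
  out <- list(diseased = 100 * x$diseased / sum(x$diseased),
              healthy = 100 * x$healthy / sum(x$healthy))
  if (!is.null(digits)) out <- lapply(out, round, digits = digits)
  out
}

#' A 2 x 2 diagnostic test table
#'
#' Counts of true/false positives/negatives for one (possibly combined)
#' dichotomous test against disease status.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @param label test name used in printing.
#' @return An object of class `binary_test_table`.
#' @export
binary_test_table <- function(tp, fp, fn, tn, label = "test") {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(abs(cells - round(cells)) > 1e-8)) stop("cell counts must be integers")
  storage.mode(cells) <- "integer"
  structure(list(tp = cells[["tp"]], fp = cells[["fp"]],
                 fn = cells[["fn"]], tn = cells[["tn"]], label = label),
            class = "binary_test_table")
}

#' @export
print.binary_test_table <- function(x, ...) {
  cat("2x2 table:", x$label, "\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("test +", "test -"), c("diseased", "healthy")))
  print(m)
  invisible(x)
}

#' Collapse a paired crosstab to one test's 2 x 2 table
#'
#' Marginalizes the 2 x 2 x 2 cross-classification over the other test,
#' preserving the diseased and healthy totals.
#'
#' @param x a [paired_crosstab()].
#' @param test `"a"` or `"b"`: which test's table to return.
#' @return A [binary_test_table()].
#' @export
marginal_table <- function(x, test = c("a", "b")) {
  stopifnot(inherits(x, "paired_crosstab"))
  test <- match.arg(test)
  d <- x$diseased; h <- x$healthy
  if (test == "a") {
    binary_test_table(tp = d[["pp"]] + d[["pn"]], fp = h[["pp"]] + h[["pn"]],
                      fn = d[["np"]] + d[["nn"]], tn = h[["np"]] + h[["nn"]],
                      label = x$test_a)
  } else {
    binary_test_table(tp = d[["pp"]] + d[["np"]], fp = h[["pp"]] + h[["np"]],
                      fn = d[["pn"]] + d[["nn"]], tn = h[["pn"]] + h[["nn"]],
                      label = x$test_b)
  }
}

#' Dichotomize a patient-level cohort at fixed cutoffs
#'
#' Assigns each subject a positive/negative call on both tests using the
#' package-wide positivity convention *score less than or equal to the cutoff
#' is positive* (low bone density and low trabecular bone score indicate
#' fragility), and tallies the paired cross-classification. Rows with missing
#' scores or disease status are dropped with a message.
#'
#' @param cohort a data frame with one row per subject containing the two
#'   score columns and a 0/1 disease indicator.
#' @param cutoff_a,cutoff_b numeric cutoffs (or [youden_cutoff()] results)
#'   for the test A and test B scores.
#' @param col_a,col_b,col_disease column names; defaults match the cohort CSV
#'   schema (`ls_bmd`, `tbs`, `fracture`).
#' @inheritParams paired_crosstab
#' @return A [paired_crosstab()].
#' @export
dichotomize <- function(cohort, cutoff_a, cutoff_b,
                        col_a = "ls_bmd", col_b = "tbs", col_disease = "fracture",
                        test_a = col_a, test_b = col_b) {
  for (cl in c(col_a, col_b, col_disease))
    if (!cl %in% names(cohort)) stop("cohort lacks column `", cl, "`")
  if (inherits(cutoff_a, "diagnostic_cutoff")) cutoff_a <- cutoff_a$value
  if (inherits(cutoff_b, "diagnostic_cutoff")) cutoff_b <- cutoff_b$value
  keep <- stats::complete.cases(cohort[, c(col_a, col_b, col_disease)])
  if (any(!keep))
    message("dichotomize: dropped ", sum(!keep), " row(s) with missing values")
  cohort <- cohort[keep, , drop = FALSE]
  if (nrow(cohort) == 0L) stop("no complete rows left to dichotomize")
  dis <- cohort[[col_disease]]
  if (!all(dis %in% c(0, 1))) stop("`", col_disease, "` must be 0/1")
  pos_a <- cohort[[col_a]] <= cutoff_a
  pos_b <- cohort[[col_b]] <= cutoff_b
  tally <- function(sel) {
    c(pp = sum(sel & pos_a & pos_b), pn = sum(sel & pos_a & !pos_b),
      np = sum(sel & !pos_a & pos_b), nn = sum(sel & !pos_a & !pos_b))
  }
  paired_crosstab(tally(dis == 1), tally(dis == 0),
                  test_a = test_a, test_b = test_b)
}

#' Read or write a paired crosstab as JSON
#'
#' The JSON schema has fields `test_a`, `test_b` and per-group objects
#' `diseased` and `healthy` with integer members `pp`, `pn`, `np`, `nn`.
#' Alternatively the file may carry a printed-percentage form: per-group
#' objects `percent` (`diseased`/`healthy`, each with the four cell
#' percentages) plus integer `totals`; it is then reconstructed with
#' [crosstab_from_percent()].
#'
#' @param path file path.
#' @param x a [paired_crosstab()] (for writing).
#' @return `read_crosstab_json()` returns a [paired_crosstab()];
#'   `write_crosstab_json()` returns `path` invisibly.
#' @export
read_crosstab_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ta <- if (!is.null(j$test_a)) j$test_a else "test A"
  tb <- if (!is.null(j$test_b)) j$test_b else "test B"
  if (!is.null(j$percent)) {
    return(crosstab_from_percent(unlist(j$percent$diseased), unlist(j$percent$healthy),
                                 n_diseased = j$totals$diseased,
                                 n_healthy = j$totals$healthy,
                                 test_a = ta, test_b = tb))
  }
  if (is.null(j$diseased) || is.null(j$healthy))
    stop("crosstab JSON needs `diseased` and `healthy` (or `percent` + `totals`)")
  paired_crosstab(unlist(j$diseased), unlist(j$healthy), test_a = ta, test_b = tb)
}

#' @rdname read_crosstab_json
#' @export
write_crosstab_json <- function(x, path) {
  stopifnot(inherits(x, "paired_crosstab"))
  jsonlite::write_json(list(test_a = x$test_a, test_b = x$test_b,
                            diseased = as.list(x$diseased),
                            healthy = as.list(x$healthy)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read or write a patient-level cohort CSV
#'
#' The cohort schema has columns `id`, `age`, `height_cm`, `weight_kg`,
#' `bmi`, `age_menopause`, `tbs`, `ls_bmd` and `fracture` (0/1). Only `tbs`,
#' `ls_bmd` and `fracture` are required for analysis; covariates may be
#' absent.
#'
#' @param path file path.
#' @param cohort a cohort data frame (for writing).
#' @return `read_cohort_csv()` returns a data frame; `write_cohort_csv()`
#'   returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, fileEncoding = "UTF-8", comment.char = "#")
  need <- c("tbs", "ls_bmd", "fracture")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort CSV lacks required column(s): ", paste(miss, collapse = ", "))
  cohort
}

#' @rdname read_cohort_csv
#' @param header_comment optional character lines written before the header,
#'   prefixed with `#` (used to record the generator seed).
#' @export
write_cohort_csv <- function(cohort, path, header_comment = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.csv(cohort, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
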