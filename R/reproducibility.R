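#' Signed relative difference between test and retest values
#'
#' `100 * (retest - test) / test`, in percent. Note the deliberate
#' asymmetry: swapping the roles gives `100 * (test - retest) / retest`,
#' not the negation.
#'
#' @param test,retest Positive numeric vectors (test must be > 0).
#' @return Signed percent differences.
#' @export
relative_difference <- function(test, retest) {
  if (any(test <= 0)) stop("test values must be > 0")
  100 * (retest - test) / test
}

#' Test-retest summary for one region
#'
#' From the signed percent differences of a set of subjects scanned twice,
#' computes the mean absolute percent difference and the sample standard
#' deviation (n - 1 denominator) of the absolute percent differences.
#'
#' @param pct_differences Numeric vector of signed percent differences
#'   (>= 2 values).
#' @return A list: `mean_abs_pct`, `sd_abs_pct`, `n`.
#' @export
trt_summary <- function(pct_differences) {
  if (length(pct_differences) < 2L) stop("at least 2 subjects required")
  a <- abs(pct_differences)
  list(mean_abs_pct = mean(a), sd_abs_pct = stats::sd(a),
       n = length(pct_differences))
}

#' Intraclass correlation coefficient for test-retest pairs
#'
#' Reproducibility index `(BIMSS - WIMSS) / (BIMSS + WIMSS)` in `[-1, 1]`,
#' with the between-individuals mean sum of squares
#' `BIMSS = 2 * sum_i (m_i - g)^2 / (n - 1)` (`m_i` the subject's
#' test/retest mean, `g` the grand mean) and the within-individual mean sum
#' of squares `WIMSS = sum_i d_i^2 / 2 / n` (`d_i = retest_i - test_i`).
#' 1 means all disagreement is between subjects (perfect repeatability);
#' -1 means all variance is within subjects.
#'
#' @param test,retest Numeric vectors of paired measurements (>= 2 pairs).
#' @return ICC in `[-1, 1]`.
#' @examples
#' icc(c(1.20, 1.13, 1.24), c(1.20, 1.15, 1.24))
#' @export
icc <- function(test, retest) {
  n <- length(test)
  if (n < 2L || length(retest) != n) stop("need >= 2 complete pairs")
  m <- (test + retest) / 2
  g <- mean(m)
  bimss <- 2 * sum((m - g)^2) / (n - 1)
  wimss <- sum((retest - test)^2 / 2) / n
  if (bimss + wimss <= 0) stop("degenerate data: no variance at all")
  (bimss - wimss) / (bimss + wimss)
}

#' Test-retest summary table over regions
#'
#' Builds the full reproducibility table from tidy paired records: per ROI
#' the signed percent differences, their mean absolute value and sample SD,
#' and the ICC. With `from_percents = TRUE` the `pct` column is consumed
#' directly instead of being recomputed from the DVR pairs (used when
#' reproducing a printed table whose per-subject percent rows carry more
#' precision than its rounded DVR values); the ICC is then only computed if
#' DVR pairs are also present.
#'
#' @param records Data frame with columns `subject_id`, `roi_name` and
#'   either `test` and `retest` or (for `from_percents`) `pct`.
#' @param from_percents Use the supplied `pct` column as-is.
#' @return Data frame: `roi_name`, `n`, `mean_abs_pct`, `sd_abs_pct`, `icc`.
#' @export
trt_table <- function(records, from_percents = FALSE) {
  need <- if (from_percents) c("subject_id", "roi_name", "pct") else
    c("subject_id", "roi_name", "test", "retest")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(records, records$roi_name), function(rr) {
    pct <- if (from_percents) rr$pct else
      relative_difference(rr$test, rr$retest)
    s <- trt_summary(pct)
    icc_val <- if (all(c("test", "retest") %in% names(rr))) {
      icc(rr$test, rr$retest)
    } else NA_real_
    data.frame(roi_name = rr$roi_name[1], n = s$n,
               mean_abs_pct = s$mean_abs_pct, sd_abs_pct = s$sd_abs_pct,
               icc = icc_val)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Published tau-tracer test-retest measurements
#'
#' Regional DVR values from five patients scanned twice (printed at two
#' decimals) together with the printed per-subject signed percent
#' differences, in 11 regions. `thk_trt_summary_published()` returns the
#' corresponding printed summary rows (mean absolute percent difference,
#' its SD, and the ICC) used as the reproduction reference.
#'
#' @return A data frame with columns `subject_id`, `roi_name`, `test`,
#'   `retest`, `pct` (the printed percent difference).
#' @export
thk_trt_records <- function() {
  path <- system.file("extdata", "thk_test_retest.tsv", package = "taupet",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname thk_trt_records
#' @export
thk_trt_summary_published <- function() {
  path <- system.file("extdata", "thk_test_retest_summary.tsv",
                      package = "taupet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
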