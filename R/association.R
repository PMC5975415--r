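check_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2x2", call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("contingency counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("contingency table has zero grand total", call. = FALSE)
  counts
}

#' Expected cell counts of a contingency table
#'
#' Under independence, the expected count of each cell is the product of its
#' marginal totals divided by the grand total. Row and column sums of the
#' expected matrix reproduce the observed marginals.
#'
#' @param counts An r x c matrix of non-negative integer counts.
#' @return Real matrix of expected counts, same shape as `counts`.
#' @examples
#' expected_counts(matrix(c(29, 1, 113, 7), 2))  # smallest cell 1.6
#' @export
expected_counts <- function(counts) {
  counts <- check_contingency(counts)
  outer(rowSums(counts), colSums(counts)) / sum(counts)
}

#' Choose between chi-square and Fisher's exact test
#'
#' The small-cell rule: when strictly more than 20% of the cells have an
#' expected count (not observed count) below 5, the chi-square approximation
#' is unreliable and the two-sided Fisher exact test is used instead; at
#' exactly 20% or less, chi-square is retained. Fisher is only supported for
#' 2x2 tables; a larger table that triggers the rule raises an error.
#'
#' @inheritParams expected_counts
#' @return `"chi_square"` or `"fisher_exact"`.
#' @examples
#' select_test(matrix(c(29, 1, 113, 7), 2))   # fisher_exact (1 of 4 cells < 5)
#' select_test(matrix(c(6, 24, 106, 14), 2))  # chi_square
#' @export
select_test <- function(counts) {
  counts <- check_contingency(counts)
  frac_small <- mean(expected_counts(counts) < 5)
  if (frac_small <= 0.20) return("chi_square")
  if (!all(dim(counts) == c(2L, 2L)))
    stop("Fisher's exact test selected for a ", nrow(counts), "x",
         ncol(counts), " table; only 2x2 is supported", call. = FALSE)
  "fisher_exact"
}

new_assoc <- function(statistic, df, p, test_used) {
  structure(list(statistic = statistic, df = df, p_value = p,
                 test_used = test_used, significant = p <= 0.05),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  if (x$test_used == "chi_square") {
    cat(sprintf("Pearson chi-square (no continuity correction): X2 = %.3f, df = %d, P = %s\n",
                x$statistic, x$df, format_p(x$p_value)))
  } else {
    cat("Fisher's exact test (two-sided): P =", format_p(x$p_value), "\n")
  }
  invisible(x)
}

#' Pearson chi-square test of association
#'
#' The uncorrected Pearson statistic sum((O - E)^2 / E) on an r x c table,
#' with (r-1)(c-1) degrees of freedom and an upper-tail chi-square p-value.
#' No Yates continuity correction is applied. A table with an expected cell
#' of zero (an empty row or column margin) is degenerate and raises an
#' error.
#'
#' @inheritParams expected_counts
#' @return Object of class `assoc_result` with `statistic`, `df`, `p_value`,
#'   `test_used = "chi_square"`.
#' @examples
#' chi_square_test(matrix(c(8, 22, 42, 78), 2))  # P = 0.386
#' @export
chi_square_test <- function(counts) {
  counts <- check_contingency(counts)
  if (any(expected_counts(counts) == 0))
    stop("degenerate table: an expected cell count is zero", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  new_assoc(unname(res$statistic), unname(res$parameter), res$p.value,
            "chi_square")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditions on both margins; the two-sided p-value is the sum of
#' hypergeometric point probabilities, over all tables with the observed
#' margins, that do not exceed the observed table's point probability (with
#' a small relative tolerance on the comparison to avoid floating-point
#' exclusion of ties). A table with a zero margin admits a single table and
#' has p = 1.
#'
#' @param counts A 2x2 matrix of non-negative integer counts.
#' @return Object of class `assoc_result` with `p_value`,
#'   `test_used = "fisher_exact"` (no statistic or df).
#' @examples
#' fisher_exact_2x2(matrix(c(27, 3, 114, 6), 2))  # P = 0.384
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- check_contingency(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("Fisher's exact test supports only 2x2 tables (got ",
         nrow(counts), "x", ncol(counts), ")", call. = FALSE)
  p <- stats::fisher.test(counts)$p.value
  new_assoc(NA_real_, NA_integer_, min(1, p), "fisher_exact")
}

#' Risk-factor association with histopathology outcome
#'
#' Builds the variable-by-histopathology contingency table for a categorical
#' cohort variable, applies the expected-count rule to choose between the
#' uncorrected chi-square and the two-sided Fisher exact test, and returns
#' counts, row percentages and the p-value — one row block of a risk-factor
#' association table.
#'
#' Recognised variables: `menopausal_status`, `parity` (classified
#' nulliparous / multiparous / grand multiparous), `bmi` (classified
#' < 25 / 25-29 / >= 30), `breastfeeding` (dichotomised < 6 vs >= 6 months;
#' exactly 6 months falls in the second class), and the binary factors
#' `family_history_ca`, `ocp_use`, `fertility_drugs`, `smoking`.
#'
#' @param cohort A validated cohort data frame.
#' @param variable One of the recognised variable names.
#' @return List of class `assoc_row`: `variable`, `counts` (categories x
#'   malignant/benign), `row_pct`, `expected` and the `assoc_result` in
#'   `test`.
#' @export
associate <- function(cohort, variable) {
  cohort <- validate_cohort(cohort)
  v <- switch(variable,
    menopausal_status = factor(cohort$menopausal_status,
                               c("premenopausal", "postmenopausal")),
    parity = classify_parity(cohort$parity),
    bmi = classify_bmi(cohort$bmi),
    breastfeeding = factor(ifelse(cohort$breastfeeding_months >= 6,
                                  ">= 6 months", "< 6 months"),
                           c("< 6 months", ">= 6 months")),
    family_history_ca = ,
    ocp_use = ,
    fertility_drugs = ,
    smoking = factor(ifelse(cohort[[variable]], "positive", "negative"),
                     c("negative", "positive")),
    stop("unrecognised association variable: ", variable, call. = FALSE)
  )
  counts <- table(v, factor(cohort$histopathology, c("malignant", "benign")))
  counts <- matrix(as.integer(counts), nrow = nlevels(v),
                   dimnames = list(levels(v), c("malignant", "benign")))
  test <- switch(select_test(counts),
                 chi_square = chi_square_test(counts),
                 fisher_exact = fisher_exact_2x2(counts))
  structure(list(variable = variable, counts = counts,
                 row_pct = 100 * counts / rowSums(counts),
                 expected = expected_counts(counts), test = test),
            class = "assoc_row")
}

#' @export
print.assoc_row <- function(x, ...) {
  cat("Association of histopathology with", x$variable, "\n")
  m <- cbind(x$counts[, 1, drop = FALSE],
             `%` = round(x$row_pct[, 1], 1),
             x$counts[, 2, drop = FALSE],
             `%` = round(x$row_pct[, 2], 1))
  print(m)
  print(x$test)
  invisible(x)
}
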