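counts <- study_summary_counts()$association

test_that("expected counts are products of marginals over the grand total", {
  e <- expected_counts(counts$family_history_ca)
  expect_equal(min(e), 8 * 30 / 150)  # 1.6
  expect_equal(rowSums(e), rowSums(counts$family_history_ca))
  expect_equal(colSums(e), colSums(counts$family_history_ca))
  e <- expected_counts(counts$menopausal_status)
  expect_equal(min(e), 38 * 30 / 150)  # 7.6
  expect_equal(expected_counts(matrix(5, 2, 2)), matrix(5, 2, 2))
  expect_error(expected_counts(matrix(0L, 2, 2)), "zero grand total")
})

test_that("the strict >20% small-expected-cell rule selects the published test per variable", {
  fisher_vars <- c("family_history_ca", "ocp_use", "fertility_drugs", "smoking")
  for (v in names(counts)) {
    expect_equal(select_test(counts[[v]]),
                 if (v %in% fisher_vars) "fisher_exact" else "chi_square",
                 info = v)
  }
  # parity: min expected 48*30/150 = 9.6, chi-square retained
  expect_equal(min(expected_counts(counts$parity)), 9.6)
  # exactly 20% small cells still permits chi-square (1 of 5... construct 2x2
  # impossible; use a table where 1 of 6 = 16.7% < 5, as in the BMI row)
  expect_equal(mean(expected_counts(counts$bmi) < 5), 1 / 6)
  expect_equal(select_test(counts$bmi), "chi_square")
  # a larger-than-2x2 table that triggers the rule is unsupported
  expect_error(select_test(matrix(c(1, 1, 1, 1, 1, 1), 3)), "only 2x2")
})

test_that("uncorrected Pearson chi-square reproduces the published p-values", {
  expect_equal(round(chi_square_test(counts$breastfeeding)$p_value, 3), 0.386)
  expect_equal(round(chi_square_test(counts$parity)$p_value, 3), 0.001)
  expect_equal(round(chi_square_test(counts$bmi)$p_value, 3), 0.048)
  expect_lt(chi_square_test(counts$menopausal_status)$p_value, 0.001)
  expect_equal(chi_square_test(counts$parity)$df, 2)
  prop <- matrix(c(10, 20, 30, 60), 2)  # proportional rows: O = E
  res <- chi_square_test(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("chi-square is permutation invariant and scales linearly with counts", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(rpois(6, 20) + 1, 2, 3)
    s <- chi_square_test(m)$statistic
    expect_equal(chi_square_test(m[2:1, c(2, 3, 1)])$statistic, s)
    expect_equal(chi_square_test(t(m))$statistic, s)
    expect_equal(chi_square_test(m * 3L)$statistic, 3 * s, tolerance = 1e-9)
  }
})

test_that("two-sided Fisher reproduces the published p-values and handles degenerate margins", {
  expect_equal(round(fisher_exact_2x2(counts$ocp_use)$p_value, 3), 0.384)
  expect_equal(fisher_exact_2x2(counts$family_history_ca)$p_value, 1)
  expect_equal(fisher_exact_2x2(counts$fertility_drugs)$p_value, 1)
  expect_equal(fisher_exact_2x2(counts$smoking)$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 4, 6), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(1L, 3, 2)), "only 2x2")
})

test_that("Fisher agrees with margin-preserving enumeration and dominates the one-sided tail", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(8:60, 1)
    r1 <- sample(1:(n - 1), 1)
    c1 <- sample(1:(n - 1), 1)
    a <- sample(max(0, r1 + c1 - n):min(r1, c1), 1)
    m <- matrix(c(a, c1 - a, r1 - a, n - r1 - c1 + a), 2)
    p2 <- fisher_exact_2x2(m)$p_value
    expect_equal(p2, oracle_fisher(m), tolerance = 1e-9,
                 info = paste(m, collapse = ","))
    lo <- max(0, r1 + c1 - n)
    one_sided <- min(sum(dhyper(lo:a, c1, n - c1, r1)),
                     sum(dhyper(a:min(r1, c1), c1, n - c1, r1)))
    expect_gte(p2 + 1e-12, one_sided)
  }
})

test_that("associate() builds the published variable-by-outcome tables from patient records", {
  co <- reference_cohort()
  for (v in names(counts)) {
    row <- associate(co, v)
    expect_equal(unname(row$counts), unname(counts[[v]]), info = v)
  }
  row <- associate(co, "menopausal_status")
  expect_equal(rownames(row$counts), c("premenopausal", "postmenopausal"))
  expect_equal(round(row$row_pct["postmenopausal", "malignant"], 1), 63.2)
  expect_error(associate(co, "age"), "unrecognised")
})
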