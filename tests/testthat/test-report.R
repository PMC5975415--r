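make_cohort_with_stages <- function(stage_counts) {
  n_mal <- sum(stage_counts)
  base <- reference_cohort()[1, ]
  co <- base[rep(1, n_mal + 2), ]
  co$patient_id <- sprintf("Q%03d", seq_len(n_mal + 2))
  co$figo_stage <- c(rep(c("I", "II", "III", "IV"), stage_counts), NA, NA)
  co$histopathology <- rep(c("malignant", "benign"), c(n_mal, 2))
  co
}

test_that("stage distribution renders the published percentages at 0 dp", {
  expect_equal(round(stage_distribution(make_cohort_with_stages(c(4, 4, 11, 11)))),
               c(I = 13, II = 13, III = 37, IV = 37))
  expect_equal(unname(stage_distribution(make_cohort_with_stages(c(5, 0, 0, 0)))),
               c(100, 0, 0, 0))
  expect_equal(unname(stage_distribution(make_cohort_with_stages(c(1, 1, 1, 1)))),
               c(25, 25, 25, 25))
  benign_only <- reference_cohort()
  benign_only <- benign_only[benign_only$histopathology == "benign", ]
  expect_error(stage_distribution(benign_only), "no malignant")
})

test_that("subtype frequencies sort by count with alphabetical tie-break", {
  co <- reference_cohort()
  t4 <- subtype_frequencies(co)
  expect_equal(t4$subtype[1], "serous cystadenoma")
  expect_equal(t4$count[1], 45)
  expect_equal(round(t4$percent[1], 1), 30.0)
  expect_equal(sum(t4$count), 150)
  expect_equal(sum(t4$percent), 100)
  tie <- co[1:10, ]
  tie$subtype <- rep(c("zz cyst", "aa cyst"), each = 5)
  expect_equal(subtype_frequencies(tie)$subtype, c("aa cyst", "zz cyst"))
})

test_that("the full study report reproduces the published tables from patient-level data", {
  rep <- run_study(reference_cohort())
  a <- rep$table6$mia
  expect_equal(round(c(a$sensitivity, a$specificity, a$ppv, a$npv,
                       a$agreement), 1), c(70.0, 96.7, 84.0, 92.8, 91.3))
  expect_equal(round(a$mcnemar_p, 3), 0.267)
  b <- rep$table6$ca125
  expect_equal(round(c(b$sensitivity, b$specificity, b$ppv, b$npv,
                       b$agreement), 1), c(83.3, 83.3, 55.6, 95.2, 83.3))
  expect_equal(round(b$mcnemar_p, 3), 0.004)
  g <- rep$table6$gynecologist
  expect_equal(round(c(g$sensitivity, g$specificity, g$agreement), 1),
               c(70.0, 85.8, 82.7))
  expect_equal(round(g$mcnemar_p, 3), 0.169)
  p <- rep$table6$mia_or_clinical
  expect_equal(round(c(p$sensitivity, p$specificity, p$ppv, p$npv,
                       p$agreement), 1), c(93.3, 82.5, 57.1, 98.0, 84.7))
  expect_lt(p$mcnemar_p, 5e-4)
  expect_equal(miascreen:::format_p(p$mcnemar_p), "< 0.001")

  expect_equal(rep$table5$mia$positive, 25)
  expect_equal(round(rep$table5$mia$positive_pct, 1), 16.7)
  expect_equal(rep$table5$ca125$positive, 45)
  expect_equal(rep$table5$gynecologist$positive, 38)
  expect_equal(rep$table5$histopathology$positive, 30)
  expect_equal(round(rep$table5$histopathology$positive_pct, 1), 20.0)

  expect_equal(round(rep$table7$mia$sensitivity, 1), 100.0)
  expect_equal(round(rep$table7$ca125$sensitivity, 1), 75.0)
  expect_equal(round(rep$table7$mia$specificity, 1), 96.7)
  expect_equal(round(rep$table7$mia$mcnemar_p, 3), 0.125)
  expect_equal(round(rep$table8$mia$sensitivity, 1), 59.1)
  expect_equal(round(rep$table8$ca125$sensitivity, 1), 86.4)
  expect_equal(round(rep$table8$mia$mcnemar_p, 3), 0.267)

  expect_equal(round(unname(rep$fig1)), c(13, 13, 37, 37))

  p_pattern <- vapply(rep$table3, function(r) r$test$test_used, character(1))
  expect_equal(unname(p_pattern[c("family_history_ca", "ocp_use",
                                  "fertility_drugs", "smoking")]),
               rep("fisher_exact", 4))
  expect_equal(unname(p_pattern[c("menopausal_status", "parity",
                                  "breastfeeding", "bmi")]),
               rep("chi_square", 4))
})

test_that("table-6 metrics agree with reconstruction from the table-5 marginals", {
  rep <- run_study(reference_cohort())
  summ <- study_summary_counts()
  for (t in rep$tests) {
    direct <- attr(rep$table6[[t]], "confusion")
    back <- reconstruct_confusion(summ$n, summ$n_malignant,
                                  rep$table5[[t]]$positive,
                                  round(rep$table6[[t]]$agreement, 1))
    expect_equal(unlist(back), unlist(direct[c("tp", "fp", "fn", "tn")]),
                 info = t)
  }
})

test_that("reports are deterministic and render to json, csv and text", {
  rep <- run_study(reference_cohort())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(rep, d1)
  write_report(run_study(reference_cohort()), d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  for (f in c("report.json", "report.txt", "table3_associations.csv",
              "table4_subtypes.csv", "table6_validity.csv",
              "table7_early_stage.csv", "table8_late_stage.csv"))
    expect_true(file.exists(file.path(d1, f)), info = f)
  j <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(j$table6$mia$sensitivity, 70)
  expect_equal(j$table6$mia$mcnemar_p_display, "0.267")
  expect_equal(j$table6$mia$cells$tp, 21)
  expect_equal(unlist(j$fig1), c(13, 13, 37, 37))
  expect_equal(j$table3$ocp_use$p_display, "0.384")
})

test_that("run_study accepts a cohort file path and an arbitrary test subset", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(sim_params(n_patients = 120), seed = 2), path)
  rep <- run_study(path, tests = c("mia", "gynecologist"))
  expect_setequal(rep$tests, c("mia", "gynecologist"))
  expect_null(rep$table6$ca125)
  expect_equal(rep$table5$mia$positive + rep$table5$mia$negative, 120)
  # structural consistency: early + late malignant = all malignant
  co <- read_cohort(path)
  n_benign <- sum(co$histopathology == "benign")
  early_mal <- nrow(stage_subset(co, "early")) - n_benign
  late_mal <- nrow(stage_subset(co, "late")) - n_benign
  expect_equal(early_mal + late_mal, sum(co$histopathology == "malignant"))
})

test_that("parallel combination dominates its components on simulated cohorts", {
  for (seed in 1:5) {
    co <- classify_cohort(generate_cohort(sim_params(n_patients = 400),
                                          seed = seed))
    mal <- co$histopathology == "malignant"
    comb <- combine_parallel(co$mia_high_risk, co$gynecologist_malignant)
    expect_gte(mean(comb[mal]),
               max(mean(co$mia_high_risk[mal]),
                   mean(co$gynecologist_malignant[mal])))
    expect_lte(mean(!comb[!mal]),
               min(mean(!co$mia_high_risk[!mal]),
                   mean(!co$gynecologist_malignant[!mal])))
  }
})
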