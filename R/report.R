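TEST_COLUMNS <- c(mia = "mia_high_risk", ca125 = "ca125_positive",
                  gynecologist = "gynecologist_malignant",
                  mia_or_clinical = "combined_positive")

TEST_LABELS <- c(mia = "MIA", ca125 = "CA 125",
                 gynecologist = "Gynecologist's assessment",
                 mia_or_clinical = "MIA and/or Clinical")

ASSOC_VARIABLES <- c("menopausal_status", "parity", "family_history_ca",
                     "ocp_use", "fertility_drugs", "smoking",
                     "breastfeeding", "bmi")

#' FIGO stage distribution of the malignant cases
#'
#' Percentage of malignant cases per FIGO stage I-IV. Full precision is
#' kept internally; the rendering convention is 0 decimal places.
#'
#' @param cohort A validated cohort with at least one malignant case.
#' @return Named numeric vector of percentages over stages I-IV.
#' @examples
#' stage_distribution(reference_cohort())  # 13 / 13 / 37 / 37
#' @export
stage_distribution <- function(cohort) {
  cohort <- validate_cohort(cohort)
  mal <- cohort[cohort$histopathology == "malignant", ]
  if (nrow(mal) == 0L)
    stop("stage distribution undefined: no malignant cases", call. = FALSE)
  counts <- table(factor(mal$figo_stage, FIGO_STAGES))
  stats::setNames(100 * as.numeric(counts) / nrow(mal), FIGO_STAGES)
}

#' Histopathological subtype frequencies
#'
#' Counts and cohort percentages per subtype, ordered by descending count
#' with alphabetical tie-break.
#'
#' @param cohort A validated cohort.
#' @return Data frame with columns `subtype`, `count`, `percent`
#'   (full precision; render at 1 dp).
#' @export
subtype_frequencies <- function(cohort) {
  cohort <- validate_cohort(cohort)
  tab <- table(cohort$subtype)
  out <- data.frame(subtype = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$subtype), , drop = FALSE]
  out$percent <- 100 * out$count / nrow(cohort)
  rownames(out) <- NULL
  out
}

#' Run the full triage evaluation study on a cohort
#'
#' One call reproduces the complete analysis: risk-factor association rows
#' (with the expected-count rule selecting chi-square or Fisher per
#' variable), subtype frequencies, per-test positive/negative counts, the
#' accuracy report of every requested screening test against histopathology
#' with its exact McNemar p-value, the same evaluations restricted to
#' early-stage (FIGO I-II) and late-stage (III-IV) cancers with the full
#' benign arm retained, and the stage distribution. The composite
#' `mia_or_clinical` test is computed from the per-patient OR of the panel
#' vote and the clinician impression, never from marginal algebra. All
#' internal values are full precision; rounding (percentages 1 dp, p-values
#' 3 dp with "< 0.001" below 0.0005) is applied only when rendering.
#'
#' @param cohort A cohort data frame, or a path to a cohort CSV.
#' @param thresholds A [marker_thresholds()] object.
#' @param tests Character subset of `"mia"`, `"ca125"`, `"gynecologist"`,
#'   `"mia_or_clinical"`.
#' @param verbose Log each association row's expected-count matrix and the
#'   test the small-cell rule selected.
#' @return Object of class `study_report` with elements `n`, `table3`
#'   (association rows), `table4` (subtypes), `table5` (per-test counts),
#'   `table6` (accuracy reports), `table7`/`table8` (early/late stage), and
#'   `fig1` (stage distribution).
#' @examples
#' rep <- run_study(reference_cohort())
#' rep$table6$mia
#' @export
run_study <- function(cohort, thresholds = marker_thresholds(),
                      tests = c("mia", "ca125", "gynecologist",
                                "mia_or_clinical"),
                      verbose = FALSE) {
  if (is.character(cohort) && length(cohort) == 1L)
    cohort <- read_cohort(cohort)
  tests <- match.arg(tests, several.ok = TRUE)
  cohort <- classify_cohort(cohort, thresholds)
  n <- nrow(cohort)
  if (n == 0L) stop("empty cohort", call. = FALSE)

  table3 <- lapply(ASSOC_VARIABLES, function(v) {
    row <- associate(cohort, v)
    if (verbose) {
      message("association '", v, "': ",
              round(100 * mean(row$expected < 5)),
              "% of expected counts < 5 -> ", row$test$test_used)
      message(paste(utils::capture.output(print(round(row$expected, 2))),
                    collapse = "\n"))
    }
    row
  })
  names(table3) <- ASSOC_VARIABLES

  table5 <- lapply(tests, function(t) {
    pos <- sum(cohort[[TEST_COLUMNS[[t]]]])
    list(positive = pos, positive_pct = 100 * pos / n,
         negative = n - pos, negative_pct = 100 * (n - pos) / n)
  })
  names(table5) <- tests
  truth_pos <- sum(cohort$histopathology == "malignant")
  table5$histopathology <- list(
    positive = truth_pos, positive_pct = 100 * truth_pos / n,
    negative = n - truth_pos, negative_pct = 100 * (n - truth_pos) / n)

  eval_group <- function(group)
    stats::setNames(lapply(tests, function(t)
      evaluate_test(cohort, TEST_COLUMNS[[t]], group)), tests)
  table6 <- eval_group("all")
  stage_tests <- intersect(tests, c("ca125", "mia"))
  has_mal <- truth_pos > 0
  table7 <- if (has_mal) stats::setNames(lapply(stage_tests, function(t)
    evaluate_test(cohort, TEST_COLUMNS[[t]], "early")), stage_tests) else NULL
  table8 <- if (has_mal) stats::setNames(lapply(stage_tests, function(t)
    evaluate_test(cohort, TEST_COLUMNS[[t]], "late")), stage_tests) else NULL

  structure(list(n = n, tests = tests,
                 table3 = table3,
                 table4 = subtype_frequencies(cohort),
                 table5 = table5,
                 table6 = table6,
                 table7 = table7,
                 table8 = table8,
                 fig1 = if (has_mal) stage_distribution(cohort) else NULL),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Ovarian-mass triage evaluation (n =", x$n, ") ==\n\n")
  cat("-- Risk-factor association with histopathology --\n")
  for (v in names(x$table3)) {
    row <- x$table3[[v]]
    star <- if (row$test$test_used == "fisher_exact") "*" else ""
    cat(sprintf("  %-20s P = %s%s\n", v, format_p(row$test$p_value), star))
  }
  cat("  (* Fisher's exact test)\n\n")
  cat("-- Histopathological diagnoses --\n")
  t4 <- x$table4
  for (i in seq_len(nrow(t4)))
    cat(sprintf("  %-30s %3d  %5.1f%%\n", t4$subtype[i], t4$count[i],
                t4$percent[i]))
  cat("\n-- Test positivity --\n")
  for (t in names(x$table5)) {
    r <- x$table5[[t]]
    lbl <- if (t == "histopathology") "Histopathology" else TEST_LABELS[[t]]
    cat(sprintf("  %-26s %3d positive (%.1f%%) / %3d negative (%.1f%%)\n",
                lbl, r$positive, r$positive_pct, r$negative, r$negative_pct))
  }
  cat("\n-- Validity vs histopathology --\n")
  for (t in x$tests) {
    cat(sprintf("  %-26s ", TEST_LABELS[[t]]))
    print(x$table6[[t]])
  }
  if (!is.null(x$table7)) {
    cat("\n-- Stage I & II cancers (benign arm retained) --\n")
    for (t in names(x$table7)) {
      cat(sprintf("  %-26s ", TEST_LABELS[[t]]))
      print(x$table7[[t]])
    }
    cat("\n-- Stage III & IV cancers (benign arm retained) --\n")
    for (t in names(x$table8)) {
      cat(sprintf("  %-26s ", TEST_LABELS[[t]]))
      print(x$table8[[t]])
    }
  }
  if (!is.null(x$fig1)) {
    cat("\n-- FIGO stage distribution of malignant cases --\n  ")
    cat(paste(sprintf("stage %s: %.0f%%", names(x$fig1), x$fig1),
              collapse = ", "), "\n")
  }
  invisible(x)
}

report_to_list <- function(x) {
  acc <- function(a) {
    out <- lapply(a[c("sensitivity", "specificity", "ppv", "npv",
                      "agreement")], function(v)
      if (is.na(v)) NULL else round(v, 1))
    out$mcnemar_p <- round(a$mcnemar_p, 3)
    out$mcnemar_p_display <- format_p(a$mcnemar_p)
    ct <- attr(a, "confusion")
    out$cells <- ct[c("tp", "fp", "fn", "tn")]
    out
  }
  list(
    n = x$n,
    table3 = lapply(x$table3, function(row) list(
      categories = rownames(row$counts),
      malignant = unname(row$counts[, "malignant"]),
      benign = unname(row$counts[, "benign"]),
      row_pct_malignant = round(unname(row$row_pct[, "malignant"]), 1),
      test_used = row$test$test_used,
      p = round(row$test$p_value, 3),
      p_display = format_p(row$test$p_value))),
    table4 = list(subtype = x$table4$subtype, count = x$table4$count,
                  percent = round(x$table4$percent, 1)),
    table5 = lapply(x$table5, function(r)
      list(positive = r$positive, positive_pct = round(r$positive_pct, 1),
           negative = r$negative, negative_pct = round(r$negative_pct, 1))),
    table6 = lapply(x$table6, acc),
    table7 = if (is.null(x$table7)) NULL else lapply(x$table7, acc),
    table8 = if (is.null(x$table8)) NULL else lapply(x$table8, acc),
    fig1 = if (is.null(x$fig1)) NULL else round(unname(x$fig1))
  )
}

#' Write a study report to disk
#'
#' Renders a [run_study()] report to any of: `report.json` (rounded, stable
#' key order, deterministic for a fixed input), per-table CSV files, and a
#' plain-text rendering identical to the console print.
#'
#' @param report A `study_report`.
#' @param dir Output directory, created if needed.
#' @param formats Subset of `"json"`, `"csv"`, `"text"`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, formats = c("json", "csv", "text")) {
  stopifnot(inherits(report, "study_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if ("json" %in% formats)
    jsonlite::write_json(report_to_list(report),
                         file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if ("text" %in% formats)
    writeLines(utils::capture.output(print(report)),
               file.path(dir, "report.txt"))
  if ("csv" %in% formats) {
    t3 <- do.call(rbind, lapply(names(report$table3), function(v) {
      row <- report$table3[[v]]
      data.frame(variable = v, category = rownames(row$counts),
                 malignant = row$counts[, "malignant"],
                 benign = row$counts[, "benign"],
                 pct_malignant = round(row$row_pct[, "malignant"], 1),
                 test_used = row$test$test_used,
                 p = format_p(row$test$p_value), row.names = NULL)
    }))
    utils::write.csv(t3, file.path(dir, "table3_associations.csv"),
                     row.names = FALSE)
    t4 <- report$table4
    t4$percent <- round(t4$percent, 1)
    utils::write.csv(t4, file.path(dir, "table4_subtypes.csv"),
                     row.names = FALSE)
    acc_df <- function(tbl) do.call(rbind, lapply(names(tbl), function(t) {
      a <- tbl[[t]]
      data.frame(test = t, sensitivity = round(a$sensitivity, 1),
                 specificity = round(a$specificity, 1),
                 ppv = round(a$ppv, 1), npv = round(a$npv, 1),
                 agreement = round(a$agreement, 1),
                 mcnemar_p = format_p(a$mcnemar_p), row.names = NULL)
    }))
    utils::write.csv(acc_df(report$table6),
                     file.path(dir, "table6_validity.csv"), row.names = FALSE)
    if (!is.null(report$table7)) {
      utils::write.csv(acc_df(report$table7),
                       file.path(dir, "table7_early_stage.csv"),
                       row.names = FALSE)
      utils::write.csv(acc_df(report$table8),
                       file.path(dir, "table8_late_stage.csv"),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
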