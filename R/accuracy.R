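#' Confusion table of a screening test against the histopathology gold standard
#'
#' Cross-tabulates paired per-patient test calls and gold-standard outcomes
#' into the four cells TP (test-positive and malignant), FP (test-positive
#' and benign), FN (test-negative and malignant) and TN (test-negative and
#' benign).
#'
#' @param test_calls Logical vector: the screening test call per patient.
#' @param truth Gold standard per patient: `"benign"`/`"malignant"` or a
#'   logical vector (`TRUE` = malignant). Paired with `test_calls`.
#' @return An object of class `confusion_table`: list with integer `tp`,
#'   `fp`, `fn`, `tn`.
#' @examples
#' confusion_table(c(TRUE, FALSE, TRUE), c("malignant", "malignant", "benign"))
#' @export
confusion_table <- function(test_calls, truth) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth)
    if (!all(truth %in% c("benign", "malignant")))
      stop("truth must be 'benign' or 'malignant'", call. = FALSE)
    truth <- truth == "malignant"
  }
  stopifnot(is.logical(test_calls), is.logical(truth))
  if (length(test_calls) != length(truth))
    stop("test_calls and truth must have the same length", call. = FALSE)
  if (anyNA(test_calls) || anyNA(truth))
    stop("test_calls and truth must not contain missing values", call. = FALSE)
  new_confusion(tp = sum(test_calls & truth), fp = sum(test_calls & !truth),
                fn = sum(!test_calls & truth), tn = sum(!test_calls & !truth))
}

new_confusion <- function(tp, fp, fn, tn) {
  cells <- c(tp = unname(tp), fp = unname(fp), fn = unname(fn),
             tn = unname(tn))
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells)))
    stop("confusion cells must be non-negative integers", call. = FALSE)
  cells <- stats::setNames(as.integer(cells), names(cells))
  structure(as.list(cells), class = "confusion_table")
}

#' @export
as.matrix.confusion_table <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
         dimnames = list(test = c("positive", "negative"),
                         histopathology = c("malignant", "benign")))
}

#' @export
print.confusion_table <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' Screening-test accuracy metrics
#'
#' Computes, as percentages: sensitivity TP/(TP+FN), specificity TN/(FP+TN),
#' positive predictive value TP/(TP+FP), negative predictive value
#' TN/(FN+TN), and total agreement (TP+TN)/n. A metric whose denominator is
#' zero is undefined and reported as `NA`, never as 0 or 100. Optionally
#' attaches the exact McNemar p-value of the test-vs-gold-standard
#' comparison.
#'
#' @param ct A [confusion_table()].
#' @param mcnemar Attach `mcnemar_p` from [mcnemar_exact()]?
#' @return Object of class `accuracy_report`: named list of full-precision
#'   percentages (`sensitivity`, `specificity`, `ppv`, `npv`, `agreement`)
#'   and optionally `mcnemar_p`. Rounding happens only at print time
#'   (1 decimal place; p-values 3 decimal places, "< 0.001" below 0.0005).
#' @examples
#' accuracy_metrics(reconstruct_confusion(150, 30, 25, 91.3))
#' @export
accuracy_metrics <- function(ct, mcnemar = FALSE) {
  stopifnot(inherits(ct, "confusion_table"))
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  if (n == 0L) stop("empty confusion table", call. = FALSE)
  pct <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
  out <- list(
    sensitivity = pct(ct$tp, ct$tp + ct$fn),
    specificity = pct(ct$tn, ct$fp + ct$tn),
    ppv = pct(ct$tp, ct$tp + ct$fp),
    npv = pct(ct$tn, ct$fn + ct$tn),
    agreement = pct(ct$tp + ct$tn, n)
  )
  if (mcnemar) out$mcnemar_p <- mcnemar_exact(ct)
  structure(out, class = "accuracy_report", confusion = ct)
}

format_p <- function(p) ifelse(p < 5e-4, "< 0.001", sprintf("%.3f", p))

#' @export
print.accuracy_report <- function(x, ...) {
  f <- function(v) if (is.na(v)) "--" else sprintf("%.1f", v)
  cat(sprintf("Sensitivity %s%%  Specificity %s%%  PPV %s%%  NPV %s%%  Agreement %s%%\n",
              f(x$sensitivity), f(x$specificity), f(x$ppv), f(x$npv),
              f(x$agreement)))
  if (!is.null(x$mcnemar_p))
    cat("Exact McNemar vs gold standard: P =", format_p(x$mcnemar_p), "\n")
  invisible(x)
}

#' Exact McNemar test of a screening test against the gold standard
#'
#' Paired exact test on the discordant cells of the 2x2 screening-vs-gold
#' table: with b = FP and c = FN, under the null the smaller discordant count
#' k = min(b, c) is Binomial(b + c, 1/2), and the two-sided p-value is the
#' doubled lower tail capped at one, `min(1, 2 * P(X <= k))`. With no
#' discordant pairs the p-value is 1. This is the exact binomial version
#' (no chi-square approximation, no continuity correction).
#'
#' @param ct A [confusion_table()], or the discordant count b with `c` given.
#' @param c Second discordant count when `ct` is given as b.
#' @return The two-sided exact p-value.
#' @examples
#' mcnemar_exact(4, 9)   # 0.267
#' mcnemar_exact(20, 5)  # 0.004
#' @export
mcnemar_exact <- function(ct, c = NULL) {
  if (inherits(ct, "confusion_table")) {
    b <- ct$fp
    c <- ct$fn
  } else {
    b <- ct
    stopifnot(!is.null(c))
  }
  stopifnot(b >= 0, c >= 0, b == floor(b), c == floor(c))
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Stage-stratified subset of a cohort
#'
#' Restricts the malignant arm to a FIGO stage group while always retaining
#' the full benign arm, so that stage-specific sensitivity is computed
#' against the same benign comparator: `"early"` keeps stage I-II malignant
#' cases, `"late"` stage III-IV, `"all"` every case.
#'
#' @param cohort A validated cohort data frame.
#' @param group `"early"`, `"late"` or `"all"`.
#' @return The subset cohort.
#' @export
stage_subset <- function(cohort, group = c("all", "early", "late")) {
  group <- match.arg(group)
  cohort <- validate_cohort(cohort)
  keep_stages <- switch(group, all = FIGO_STAGES,
                        early = c("I", "II"), late = c("III", "IV"))
  cohort[cohort$histopathology == "benign" |
           cohort$figo_stage %in% keep_stages, , drop = FALSE]
}

#' Reconstruct integer confusion cells from published summary statistics
#'
#' Recovers the unique 2x2 confusion table from four summaries a study
#' typically prints: cohort size n, number of gold-standard positives d,
#' number of test positives t, and total agreement as a rounded percentage.
#' The cells satisfy tp + fn = d, tp + fp = t and tp + tn = A where A is the
#' agreement count, so tp = (A - n + d + t) / 2. Because the printed
#' percentage is rounded, A is searched over the rounding neighbourhood
#' (round(pct/100 * n) and its +/- 1 neighbours) and the solution whose
#' recomputed agreement matches the printed value at 1 decimal place is
#' returned.
#'
#' @param n_total Cohort size.
#' @param n_disease_pos Gold-standard positive count.
#' @param n_test_pos Test positive count.
#' @param agreement_pct Printed total agreement, percent (1 dp).
#' @return A [confusion_table()].
#' @examples
#' reconstruct_confusion(150, 30, 25, 91.3)  # tp 21, fp 4, fn 9, tn 116
#' reconstruct_confusion(150, 30, 45, 83.3)  # tp 25, fp 20, fn 5, tn 100
#' @export
reconstruct_confusion <- function(n_total, n_disease_pos, n_test_pos,
                                  agreement_pct) {
  stopifnot(n_total > 0, n_disease_pos >= 0, n_test_pos >= 0,
            n_disease_pos <= n_total, n_test_pos <= n_total,
            agreement_pct >= 0, agreement_pct <= 100)
  a0 <- round(agreement_pct / 100 * n_total)
  for (a in a0 + c(0L, -1L, 1L)) {
    tp2 <- a - n_total + n_disease_pos + n_test_pos
    if (a < 0 || a > n_total || tp2 %% 2 != 0) next
    tp <- tp2 / 2
    fp <- n_test_pos - tp
    fn <- n_disease_pos - tp
    tn <- n_total - tp - fp - fn
    if (min(tp, fp, fn, tn) < 0) next
    if (round(100 * (tp + tn) / n_total, 1) == round(agreement_pct, 1))
      return(new_confusion(tp, fp, fn, tn))
  }
  stop("no non-negative integer confusion table is consistent with ",
       "n = ", n_total, ", disease+ = ", n_disease_pos, ", test+ = ",
       n_test_pos, ", agreement = ", agreement_pct, "%", call. = FALSE)
}

#' Evaluate a screening-test column of a cohort
#'
#' Convenience wrapper: subsets the cohort to a stage group, cross-tabulates
#' the named logical test column against histopathology and returns the
#' accuracy report with the exact McNemar p-value attached.
#'
#' @param cohort A cohort, already carrying test-call columns (see
#'   [classify_cohort()]).
#' @param test_col Name of a logical column, e.g. `"mia_high_risk"`.
#' @inheritParams stage_subset
#' @return An [accuracy_metrics()] report.
#' @export
evaluate_test <- function(cohort, test_col, group = "all") {
  if (!test_col %in% names(cohort))
    stop("no such test column: ", test_col, call. = FALSE)
  sub <- stage_subset(cohort, group)
  accuracy_metrics(confusion_table(sub[[test_col]], sub$histopathology),
                   mcnemar = TRUE)
}
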