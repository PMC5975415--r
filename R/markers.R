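MARKERS <- c("ca125", "b2m", "transferrin", "apoa1", "prealbumin")

check_menopausal <- function(menopausal_status) {
  if (!all(menopausal_status %in% c("premenopausal", "postmenopausal")))
    stop("menopausal_status must be 'premenopausal' or 'postmenopausal'",
         call. = FALSE)
  menopausal_status
}

#' Call a single marker positive or negative against its reference threshold
#'
#' CA 125 and beta-2 microglobulin are positive strictly above their upper
#' limits (the CA 125 limit depends on menopausal status); transferrin,
#' apolipoprotein A1 and prealbumin are positive strictly below their lower
#' limits. A value exactly at its limit is within the normal range (negative).
#' Vectorised over `value` (and `menopausal_status` for CA 125).
#'
#' @param marker One of `"ca125"`, `"b2m"`, `"transferrin"`, `"apoa1"`,
#'   `"prealbumin"`.
#' @param value Measured serum level (IU/L for CA 125, g/L otherwise);
#'   must be present and non-negative.
#' @param menopausal_status `"premenopausal"` or `"postmenopausal"`;
#'   only consulted for CA 125.
#' @param thresholds A [marker_thresholds()] object.
#' @return Logical vector: `TRUE` where the marker is positive.
#' @examples
#' classify_marker("ca125", c(50, 250), "premenopausal")
#' classify_marker("ca125", 50, "postmenopausal")
#' classify_marker("transferrin", 2.24)  # at the limit: negative
#' @export
classify_marker <- function(marker, value,
                            menopausal_status = "premenopausal",
                            thresholds = marker_thresholds()) {
  marker <- match.arg(marker, MARKERS)
  if (length(value) == 0L || anyNA(value))
    stop("missing value for marker '", marker, "'", call. = FALSE)
  if (any(value < 0))
    stop("marker '", marker, "' has negative values", call. = FALSE)
  switch(marker,
    ca125 = {
      check_menopausal(menopausal_status)
      cut <- ifelse(menopausal_status == "postmenopausal",
                    thresholds$ca125_postmenopausal_upper,
                    thresholds$ca125_premenopausal_upper)
      value > cut
    },
    b2m = value > thresholds$b2m_upper,
    transferrin = value < thresholds$transferrin_lower,
    apoa1 = value < thresholds$apoa1_lower,
    prealbumin = value < thresholds$prealbumin_lower
  )
}

#' Modified multivariate index assay: the 3-of-5 positivity vote
#'
#' Calls each of the five markers against its reference threshold and flags a
#' mass as high risk of malignancy when at least three of the five calls are
#' positive; two or fewer positives is low risk. All five values must be
#' present: the vote is undefined on a partial panel and never degrades to a
#' 3-of-4 rule.
#'
#' @param panel Named list or vector with elements `ca125`, `b2m`,
#'   `transferrin`, `apoa1`, `prealbumin` (one patient), or a data frame with
#'   those columns (one row per patient).
#' @param menopausal_status `"premenopausal"` or `"postmenopausal"`, recycled
#'   or per patient.
#' @inheritParams classify_marker
#' @return For a single panel, an object of class `mia_result` with elements
#'   `calls` (named logical vector), `n_positive` and `high_risk`. For a data
#'   frame, a data frame with logical call columns plus `n_positive` and
#'   `high_risk`.
#' @examples
#' mia_classify(list(ca125 = 250, b2m = 3.1, transferrin = 2.0,
#'                   apoa1 = 1.5, prealbumin = 0.25), "premenopausal")
#' @export
mia_classify <- function(panel, menopausal_status,
                         thresholds = marker_thresholds()) {
  if (is.data.frame(panel)) {
    miss <- setdiff(MARKERS, names(panel))
    if (length(miss))
      stop("panel is missing marker column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    check_menopausal(menopausal_status)
    if (length(menopausal_status) == 1L)
      menopausal_status <- rep(menopausal_status, nrow(panel))
    na_rows <- which(Reduce(`|`, lapply(panel[MARKERS], is.na)))
    if (length(na_rows))
      stop("missing marker value(s) in row(s): ",
           paste(utils::head(na_rows, 10L), collapse = ", "), call. = FALSE)
    calls <- lapply(MARKERS, function(m)
      classify_marker(m, panel[[m]], menopausal_status, thresholds))
    names(calls) <- paste0(MARKERS, "_positive")
    out <- as.data.frame(calls)
    out$n_positive <- Reduce(`+`, calls)
    out$high_risk <- out$n_positive >= 3L
    return(out)
  }
  panel <- as.list(panel)
  miss <- MARKERS[!vapply(MARKERS, function(m)
    !is.null(panel[[m]]) && length(panel[[m]]) == 1L && !is.na(panel[[m]]),
    logical(1))]
  if (length(miss))
    stop("missing marker value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  calls <- vapply(MARKERS, function(m)
    classify_marker(m, panel[[m]], menopausal_status, thresholds), logical(1))
  n_pos <- sum(calls)
  structure(list(calls = calls, n_positive = n_pos, high_risk = n_pos >= 3L),
            class = "mia_result")
}

#' @export
print.mia_result <- function(x, ...) {
  cat("MIA 3-of-5 vote:", x$n_positive, "of 5 markers positive ->",
      if (x$high_risk) "HIGH risk of malignancy" else "low risk of malignancy",
      "\n")
  pos <- names(x$calls)[x$calls]
  if (length(pos)) cat("  positive:", paste(pos, collapse = ", "), "\n")
  invisible(x)
}

#' Standalone CA 125 classification
#'
#' The referral criterion used on its own: suspicious when CA 125 is strictly
#' above 200 IU/L in premenopausal women or strictly above 35 IU/L in
#' postmenopausal women. Identical to the CA 125 component call inside the
#' panel vote. Vectorised.
#'
#' @param ca125 CA 125 level, IU/L.
#' @inheritParams classify_marker
#' @return Logical: `TRUE` where suspicious for malignancy.
#' @examples
#' ca125_classify(c(200, 201), "premenopausal")
#' ca125_classify(36, "postmenopausal")
#' @export
ca125_classify <- function(ca125, menopausal_status,
                           thresholds = marker_thresholds()) {
  classify_marker("ca125", ca125, menopausal_status, thresholds)
}

#' Combine two screening tests in parallel
#'
#' Parallel combination: the composite test is positive when either or both
#' component tests are positive (logical OR). Raises sensitivity at the cost
#' of specificity.
#'
#' @param result_a,result_b Logical vectors of test calls, paired by patient.
#' @return Logical vector of combined calls.
#' @examples
#' combine_parallel(c(TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE))
#' @export
combine_parallel <- function(result_a, result_b) {
  stopifnot(is.logical(result_a), is.logical(result_b),
            length(result_a) == length(result_b))
  result_a | result_b
}

#' Append screening-test calls to a cohort
#'
#' Runs the panel vote, the standalone CA 125 rule and the parallel
#' combination of the panel with the clinician impression over a validated
#' cohort, appending columns `mia_n_positive`, `mia_high_risk`,
#' `ca125_positive` and `combined_positive`.
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @inheritParams classify_marker
#' @return The cohort with four columns appended.
#' @export
classify_cohort <- function(cohort, thresholds = marker_thresholds()) {
  cohort <- validate_cohort(cohort)
  mia <- mia_classify(cohort[MARKERS], cohort$menopausal_status, thresholds)
  cohort$mia_n_positive <- mia$n_positive
  cohort$mia_high_risk <- mia$high_risk
  cohort$ca125_positive <- ca125_classify(cohort$ca125,
                                          cohort$menopausal_status, thresholds)
  cohort$combined_positive <- combine_parallel(cohort$mia_high_risk,
                                               cohort$gynecologist_malignant)
  cohort
}
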