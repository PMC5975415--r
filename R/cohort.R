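#' Cohort CSV column schema
#'
#' Column order and types of the per-patient cohort CSV understood by
#' [read_cohort()] and produced by [write_cohort()] and [generate_cohort()].
#' Booleans are encoded `TRUE`/`FALSE`; missing marker values and the absent
#' `figo_stage` of benign cases are empty fields; `months_since_last_menses`
#' may be empty only when `menses_unsure` is `TRUE`.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "age", "months_since_last_menses", "menses_unsure",
    "parity", "bmi", "family_history_ca", "ocp_use", "fertility_drugs",
    "smoking", "breastfeeding_months", "ca125", "b2m", "transferrin",
    "apoa1", "prealbumin", "gynecologist_malignant", "histopathology",
    "subtype", "figo_stage")
}

#' Derive menopausal status from menstrual history and age
#'
#' A woman is postmenopausal when her last menses was at least 12 months ago,
#' or, when she is unsure of her menses, when she is aged 50 or older.
#' The age rule applies only in the unsure case: a woman of 50+ with a known
#' recent menses (< 12 months) is premenopausal. A missing months value
#' without the unsure flag is a contradictory record and raises an error
#' rather than being imputed. Vectorised.
#'
#' @param months_since_last_menses Integer months, or `NA` when unknown.
#' @param age Age in completed years, at least 18.
#' @param unsure Logical: the woman is unsure of her menses.
#' @return Character vector, `"premenopausal"` or `"postmenopausal"`.
#' @examples
#' derive_menopausal_status(14, 45, FALSE)  # postmenopausal
#' derive_menopausal_status(NA, 52, TRUE)   # postmenopausal by the age rule
#' derive_menopausal_status(3, 30, FALSE)   # premenopausal
#' @export
derive_menopausal_status <- function(months_since_last_menses, age, unsure) {
  n <- max(length(months_since_last_menses), length(age), length(unsure))
  months <- rep_len(months_since_last_menses, n)
  age <- rep_len(age, n)
  unsure <- rep_len(unsure, n)
  if (anyNA(age) || any(age < 18))
    stop("age must be known and at least 18", call. = FALSE)
  if (anyNA(unsure))
    stop("menses_unsure must be TRUE or FALSE", call. = FALSE)
  bad <- is.na(months) & !unsure
  if (any(bad))
    stop("months_since_last_menses unknown without the unsure flag ",
         "(contradictory record) at position(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "), call. = FALSE)
  post <- ifelse(unsure & is.na(months), age >= 50, !is.na(months) & months >= 12)
  ifelse(post, "postmenopausal", "premenopausal")
}

#' Classify parity
#'
#' Nulliparous (0 deliveries), multiparous (1-4), grand multiparous (5 or
#' more). Vectorised.
#'
#' @param parity Non-negative integer number of deliveries.
#' @return Factor with levels `nulliparous`, `multiparous`,
#'   `grand_multiparous`.
#' @examples
#' classify_parity(c(0, 4, 5))
#' @export
classify_parity <- function(parity) {
  if (anyNA(parity) || any(parity < 0) || any(parity != floor(parity)))
    stop("parity must be a known non-negative integer", call. = FALSE)
  cut(parity, breaks = c(-Inf, 0, 4, Inf),
      labels = c("nulliparous", "multiparous", "grand_multiparous"))
}

#' Classify body-mass index
#'
#' Normal (< 25), overweight (25 to < 30), obese (30 or more), in kg/m^2.
#' The boundaries follow the WHO convention: 25 is overweight, 30 is obese.
#' Vectorised.
#'
#' @param bmi Positive BMI, kg/m^2.
#' @return Factor with levels `normal`, `overweight`, `obese`.
#' @examples
#' classify_bmi(c(24.9, 25, 31.2))
#' @export
classify_bmi <- function(bmi) {
  if (anyNA(bmi) || any(bmi <= 0))
    stop("bmi must be known and positive", call. = FALSE)
  cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"))
}

FIGO_STAGES <- c("I", "II", "III", "IV")

#' Validate a cohort data frame
#'
#' Checks the schema and per-row invariants of a cohort: required columns
#' present; age at least 18; BMI positive; parity a non-negative integer;
#' histopathology one of `benign`/`malignant`; `figo_stage` present if and
#' only if the mass is malignant; marker values non-negative where present;
#' menstrual history non-contradictory. Derives the `menopausal_status`
#' column when absent. Errors carry the offending row numbers.
#'
#' @param cohort A data frame in the [cohort_columns()] schema.
#' @return The validated cohort, with `menopausal_status` present.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(cohort_columns(), names(cohort))
  if (length(miss))
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(cohort) == 0L) {
    cohort$menopausal_status <- character(0)
    return(cohort)
  }

  fail <- function(rows, what) {
    if (length(rows))
      stop("invalid cohort record(s), row ",
           paste(utils::head(rows, 10L), collapse = ", "), ": ", what,
           call. = FALSE)
  }
  for (col in c("menses_unsure", "family_history_ca", "ocp_use",
                "fertility_drugs", "smoking", "gynecologist_malignant")) {
    v <- cohort[[col]]
    if (!is.logical(v)) {
      v <- as.logical(v)
      cohort[[col]] <- v
    }
    fail(which(is.na(v)), paste0(col, " must be TRUE or FALSE"))
  }
  fail(which(is.na(cohort$age) | cohort$age < 18), "age must be >= 18")
  fail(which(is.na(cohort$bmi) | cohort$bmi <= 0), "bmi must be positive")
  fail(which(is.na(cohort$parity) | cohort$parity < 0 |
               cohort$parity != floor(cohort$parity)),
       "parity must be a non-negative integer")
  fail(which(is.na(cohort$breastfeeding_months) | cohort$breastfeeding_months < 0),
       "breastfeeding_months must be non-negative")
  fail(which(!cohort$histopathology %in% c("benign", "malignant")),
       "histopathology must be 'benign' or 'malignant'")
  stage <- as.character(cohort$figo_stage)
  stage[!is.na(stage) & stage == ""] <- NA_character_
  cohort$figo_stage <- stage
  fail(which(cohort$histopathology == "malignant" &
               (is.na(stage) | !stage %in% FIGO_STAGES)),
       "malignant cases need a figo_stage in I-IV")
  fail(which(cohort$histopathology == "benign" & !is.na(stage)),
       "figo_stage must be absent for benign cases")
  for (m in MARKERS)
    fail(which(!is.na(cohort[[m]]) & cohort[[m]] < 0),
         paste0(m, " must be non-negative"))
  fail(which(is.na(cohort$months_since_last_menses) & !cohort$menses_unsure),
       "months_since_last_menses unknown without menses_unsure")
  if (is.null(cohort$menopausal_status)) {
    cohort$menopausal_status <- derive_menopausal_status(
      cohort$months_since_last_menses, cohort$age, cohort$menses_unsure)
  } else {
    fail(which(!cohort$menopausal_status %in%
                 c("premenopausal", "postmenopausal")),
         "menopausal_status must be premenopausal/postmenopausal")
  }
  cohort
}

#' Read and write per-patient cohort files
#'
#' Comma-separated UTF-8 with a header row in the [cohort_columns()] schema.
#' Every record is validated on read ([validate_cohort()]); the row number of
#' any invalid record is reported. `write_cohort()` then `read_cohort()`
#' round-trips all fields of a valid cohort.
#'
#' @param path Path to a cohort CSV file.
#' @return `read_cohort()`: a validated cohort data frame with the derived
#'   `menopausal_status` column. `write_cohort()`: `path`, invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  miss <- setdiff(cohort_columns(), gsub('"', "", header))
  if (length(miss))
    stop("cohort file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  cls <- c(patient_id = "character", histopathology = "character",
           subtype = "character", figo_stage = "character")
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = cls, na.strings = "")
  if (nrow(cohort) == 0L) cohort$subtype <- character(0)
  validate_cohort(cohort)
}

#' @param cohort A validated cohort data frame.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(cohort[intersect(c(cohort_columns(), "menopausal_status"),
                                    names(cohort))],
                   path, row.names = FALSE, na = "")
  invisible(path)
}
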