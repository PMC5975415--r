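#' Deterministic reconstruction of the published evaluation cohort
#'
#' Builds a synthetic patient-level cohort of 150 women that is exactly
#' consistent with every summary table of the published evaluation study the
#' package's defaults emulate: 30 malignant / 120 benign; FIGO stages
#' 4/4/11/11 among the malignant cases (13/13/37/37%); panel-vote confusion
#' cells (TP 21, FP 4, FN 9, TN 116) with all 8 early-stage cancers
#' panel-positive; standalone CA 125 cells (25, 20, 5, 100) with 6 of 8
#' early-stage cancers positive; clinician-impression cells (21, 17, 9, 103)
#' overlapping the panel vote so their parallel combination gives
#' (28, 21, 2, 99); the menopause, parity, BMI, family-history, OCP,
#' fertility-drug, smoking and breastfeeding margins of the risk-factor
#' table; and the subtype frequency table.
#'
#' Marker values are synthetic: they are placed on the required side of each
#' threshold to realise the intended per-patient calls (a panel-positive
#' patient carries exactly three positive markers), not drawn from any
#' distribution. Joint structure beyond the published margins (e.g. which
#' postmenopausal patient smokes) is arbitrary but fixed, so the cohort is
#' byte-stable across calls and the full pipeline reproduces the printed
#' tables from patient-level data.
#'
#' @return A validated cohort data frame of 150 records.
#' @examples
#' rep <- run_study(reference_cohort())
#' round(rep$table6$mia$sensitivity, 1)  # 70
#' @export
reference_cohort <- function() {
  th <- marker_thresholds()

  # --- malignant arm: 30 patients, ordered stage I(4) II(4) III(11) IV(11)
  n_mal <- 30L
  stage <- rep(c("I", "II", "III", "IV"), c(4, 4, 11, 11))
  mia <- seq_len(n_mal) <= 21L            # all 8 early + 13 late positive
  ca125 <- c(rep(c(TRUE, FALSE), c(6, 2)),          # early: 6 of 8
             rep(c(TRUE, FALSE), c(13, 0)),         # late MIA+: all 13
             rep(c(TRUE, FALSE), c(6, 3)))          # late MIA-: 6 of 9
  gyn <- c(rep(TRUE, 14), rep(FALSE, 7),   # 14 of the 21 MIA+ also gyn+
           rep(TRUE, 7), rep(FALSE, 2))    # 7 of the 9 MIA-; 2 neither
  post <- seq_len(n_mal) <= 24L
  mal <- data.frame(
    histopathology = "malignant",
    figo_stage = stage,
    mia = mia, ca125_pos = ca125, gyn = gyn, post = post,
    parity = rep(c(0L, 2L, 5L), c(8, 4, 18)),
    bmi = rep(c(27, 32), c(14, 16)),
    family_history_ca = seq_len(n_mal) <= 1L,
    ocp_use = seq_len(n_mal) <= 3L,
    fertility_drugs = seq_len(n_mal) <= 2L,
    smoking = seq_len(n_mal) <= 1L,
    breastfeeding_months = rep(c(12, 2), c(22, 8)),
    subtype = rep(c("serous cystadenocarcinoma", "endometrioid adenocarcinoma",
                    "mucinous cystadenocarcinoma", "krukenberg's tumor",
                    "granulosa cell cancer"), c(14, 8, 3, 3, 2)),
    stringsAsFactors = FALSE
  )

  # --- benign arm: 120 patients; panel-positive and clinician-positive
  # sets are disjoint so the parallel combination has 21 false positives
  n_ben <- 120L
  ben <- data.frame(
    histopathology = "benign",
    figo_stage = NA_character_,
    mia = seq_len(n_ben) <= 4L,
    ca125_pos = seq_len(n_ben) <= 20L,
    gyn = seq_len(n_ben) > 4L & seq_len(n_ben) <= 21L,
    post = seq_len(n_ben) <= 14L,
    parity = rep(c(0L, 2L, 5L), c(40, 50, 30)),
    bmi = rep(c(22, 27, 32), c(18, 38, 64)),
    family_history_ca = seq_len(n_ben) <= 7L,
    ocp_use = seq_len(n_ben) <= 6L,
    fertility_drugs = seq_len(n_ben) <= 8L,
    smoking = seq_len(n_ben) <= 4L,
    breastfeeding_months = rep(c(12, 2), c(78, 42)),
    subtype = rep(c("serous cystadenoma", "dermoid", "endometrioma",
                    "mucinous cystadenoma", "hemorrhagic luteal cyst",
                    "follicular cyst"), c(45, 28, 18, 16, 7, 6)),
    stringsAsFactors = FALSE
  )

  d <- rbind(mal, ben)
  n <- nrow(d)

  # marker levels realising the intended calls: a panel-positive patient has
  # exactly three positive markers (CA 125 and B2M/transferrin/ApoA1 as needed)
  ca_cut <- ifelse(d$post, th$ca125_postmenopausal_upper,
                   th$ca125_premenopausal_upper)
  d$ca125 <- ifelse(d$ca125_pos, 1.5 * ca_cut, 0.5 * ca_cut)
  d$b2m <- ifelse(d$mia, th$b2m_upper + 0.6, th$b2m_upper - 0.5)
  d$transferrin <- ifelse(d$mia, th$transferrin_lower - 0.4,
                          th$transferrin_lower + 0.8)
  d$apoa1 <- ifelse(d$mia & !d$ca125_pos, th$apoa1_lower - 0.3,
                    th$apoa1_lower + 0.5)
  d$prealbumin <- th$prealbumin_lower + 0.05

  cohort <- data.frame(
    patient_id = sprintf("S%03d", seq_len(n)),
    age = ifelse(d$post, 60L, 35L),
    months_since_last_menses = ifelse(d$post, 24L, 2L),
    menses_unsure = FALSE,
    parity = d$parity,
    bmi = d$bmi,
    family_history_ca = d$family_history_ca,
    ocp_use = d$ocp_use,
    fertility_drugs = d$fertility_drugs,
    smoking = d$smoking,
    breastfeeding_months = d$breastfeeding_months,
    ca125 = d$ca125,
    b2m = d$b2m,
    transferrin = d$transferrin,
    apoa1 = d$apoa1,
    prealbumin = d$prealbumin,
    gynecologist_malignant = d$gyn,
    histopathology = d$histopathology,
    subtype = d$subtype,
    figo_stage = d$figo_stage,
    stringsAsFactors = FALSE
  )
  validate_cohort(cohort)
}

#' Published summary counts of the reference evaluation study
#'
#' The printed summary statistics that [reference_cohort()] is reconstructed
#' from, in machine-readable form: the risk-factor contingency tables
#' (categories x malignant/benign), the per-test positive counts and
#' agreement percentages that determine the confusion cells via
#' [reconstruct_confusion()], and the stage-stratified cells.
#'
#' @return Nested list with elements `n`, `n_malignant`, `association`
#'   (named list of count matrices), `tests` (per test: `n_positive` and
#'   `agreement_pct`), and `stage_cells` (early/late confusion cells for the
#'   panel vote and CA 125).
#' @export
study_summary_counts <- function() {
  m <- function(...) {
    v <- c(...)
    matrix(v, ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("malignant", "benign")))
  }
  list(
    n = 150L, n_malignant = 30L,
    association = list(
      menopausal_status = m(6, 106, 24, 14),
      parity = m(8, 40, 4, 50, 18, 30),
      family_history_ca = m(29, 113, 1, 7),
      ocp_use = m(27, 114, 3, 6),
      fertility_drugs = m(28, 112, 2, 8),
      smoking = m(29, 116, 1, 4),
      breastfeeding = m(8, 42, 22, 78),
      bmi = m(0, 18, 14, 38, 16, 64)
    ),
    tests = list(
      mia = list(n_positive = 25L, agreement_pct = 91.3),
      ca125 = list(n_positive = 45L, agreement_pct = 83.3),
      gynecologist = list(n_positive = 38L, agreement_pct = 82.7),
      mia_or_clinical = list(n_positive = 49L, agreement_pct = 84.7)
    ),
    stage_cells = list(
      early = list(mia = c(tp = 8, fp = 4, fn = 0, tn = 116),
                   ca125 = c(tp = 6, fp = 20, fn = 2, tn = 100)),
      late = list(mia = c(tp = 13, fp = 4, fn = 9, tn = 116),
                  ca125 = c(tp = 19, fp = 20, fn = 3, tn = 100))
    )
  )
}
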