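---
title: "Methods: the modified multivariate index assay and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the modified multivariate index assay and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miascreen)
```

## The screening rule

The multivariate index assay (MIA) for ovarian masses combines five serum
analytes: CA 125, beta-2 microglobulin (B2M), transferrin, apolipoprotein
A1 (ApoA1) and prealbumin (transthyretin). The commercial score is
proprietary; the rule implemented here is the software-independent
modification designed for settings without access to it. Each marker is
dichotomised against its kit reference range — CA 125 and B2M positive
above their upper limits, the three carrier proteins positive below their
lower limits, reflecting their opposite movement in malignancy — and a
mass is called high risk when at least three of the five calls are
positive.

Three boundary conventions are the package's own, made once and applied
everywhere:

* **Strict inequalities.** The reference material describes positivity as
  "above the upper limit" / "below the lower limit", and the standalone
  CA 125 referral criterion is printed as "> 200 U/ml". A value exactly at
  a limit is therefore inside the normal range (negative).
* **One CA 125 cutoff.** The menopause-dependent CA 125 limits
  (200 IU/L premenopausal, 35 IU/L postmenopausal) are used both inside
  the panel vote and for the standalone CA 125 test; no separate
  within-panel cutoff exists. IU/L and U/ml are numerically
  interchangeable for CA 125, so one canonical unit (IU/L) is stored and
  no conversion is performed.
* **No partial votes.** A missing marker makes the vote undefined and
  raises an error naming the absent markers. A triage rule must not
  silently degrade to a 3-of-4 vote.

Menopausal status is derived from the 12-month amenorrhoea rule; age ≥ 50
decides only when the woman is unsure of her menses, so a woman of 50+
with a known menses three months ago is premenopausal. A missing months
value without the unsure flag is a contradictory record and is rejected
rather than imputed. Parity is classed 0 / 1–4 / ≥ 5 and BMI
< 25 / 25–30 / ≥ 30 kg/m²; the printed BMI labels ("25–29", "≥ 30") leave
[29, 30) unassigned, and the package resolves this as overweight = [25, 30)
per the WHO convention the labels abbreviate. Breastfeeding dichotomises
at 6 months with the boundary in the "≥ 6" class.

## Evaluation statistics

Screening tests are scored against surgical histopathology as gold
standard. With cells TP, FP, FN, TN:

* sensitivity = TP/(TP+FN) × 100, specificity = TN/(FP+TN) × 100,
  PPV = TP/(TP+FP) × 100, NPV = TN/(FN+TN) × 100,
  agreement = (TP+TN)/n × 100. A zero denominator yields an absent (`NA`)
  metric, never 0 or 100 — silent extremes would corrupt comparisons.
* **Exact McNemar.** The paired comparison of a test with the gold
  standard uses the exact binomial two-sided McNemar test on the
  discordant cells b = FP, c = FN: p = min(1, 2·P(X ≤ min(b, c))) with
  X ~ Binomial(b + c, ½), and p = 1 when b = c (including b = c = 0). The
  chi-square approximation and the continuity-corrected variant were
  rejected because only the exact form reproduces reference values such as
  0.267 for (b, c) = (4, 9) and 0.004 for (20, 5); the doubled-smaller-tail
  convention matches the SPSS "exact sig." definition common in the
  clinical literature.
* **Association tests.** Risk-factor tables are tested with the
  uncorrected Pearson chi-square (Yates correction rejected on the same
  reproduction grounds), replaced by the two-sided Fisher exact test when
  strictly more than 20% of the *expected* cells (row total × column
  total / n) are below 5 — exactly 20% still permits chi-square. The
  Fisher two-sided p is the sum of hypergeometric point probabilities not
  exceeding the observed table's, with a 1e−7 relative guard on the
  comparison so floating-point noise cannot exclude ties; only 2×2 Fisher
  is supported, and a larger table triggering the rule is an explicit
  error rather than a silent approximation. Association rows are flagged
  significant at p ≤ 0.05.
* **Stage stratification.** Early (FIGO I–II) and late (III–IV) analyses
  restrict the malignant arm only; the full benign arm is always retained,
  so stage-specific sensitivity is computed against the same comparator.

Percentages are rendered at 1 decimal place and p-values at 3
(as "< 0.001" below 0.0005); all internal computation is full precision
and rounding happens only at render time.

## Reconstructing confusion cells from printed summaries

Published accuracy tables often print only marginals: n, the number of
diseased, the number of test positives t, and agreement as a rounded
percentage. The cells then satisfy tp + fn = d, tp + fp = t and
tp + tn = A, giving tp = (A − n + d + t)/2 for the agreement count A.
`reconstruct_confusion()` searches A over round(pct/100·n) and its ±1
neighbours, requires integrality and non-negativity, and accepts the
solution whose recomputed agreement matches the printed value at 1 dp.
For n ≤ 500 the 1-dp rounding pins A uniquely (adjacent counts differ by
at least 0.2 percentage points), which the round-trip property tests
exercise on random tables. `reference_cohort()` extends the idea to a full
patient-level reconstruction: a deterministic synthetic cohort whose
per-patient calls jointly reproduce every published margin (confusion
cells of all four tests including their parallel combination, the
stage-stratified cells, the risk-factor tables, subtype frequencies and
the stage distribution). Its marker values are placed on the required side
of each threshold, not drawn from a distribution, and joint structure
beyond the printed margins is arbitrary but fixed.

## The synthetic cohort generator

`generate_cohort()` emulates the kind of cohort the analysis assumes:
`n` women with ovarian masses (default 150), malignancy prevalence 0.20,
class-conditional menopause rates 14/120 (benign) and 24/30 (malignant),
FIGO stage probabilities (0.13, 0.13, 0.37, 0.37) among malignant cases,
risk-factor covariate probabilities equal to the per-class row proportions
of the association table, per-class subtype frequencies, and a clinician
impression drawn Bernoulli(0.70) for malignant and Bernoulli(1 − 0.858)
for benign cases. Class labels are drawn first; everything else is
conditionally independent given class. One integer seed drives a single
generator stream, record order is generation order, and the caller's RNG
state is restored afterwards.

Marker levels are log-normal — serum tumour markers are positive and
right-skewed, and the location/scale parameterisation keeps calibration
transparent. No per-class distributions are published, so the calibration
is analytic and self-contained (`calibrate_marker_dists()`): the CA 125
positivity rate per class is fixed at the standalone operating point
(0.833 / 0.167), the four remaining markers share a per-class rate solved
by `uniroot` so that the exact Poisson-binomial 3-of-5 tail
(`vote_positive_prob()`, enumeration of all 2⁵ patterns) equals the target
panel operating point (0.70 sensitivity, 0.967 specificity), and rates are
converted to log-normal locations against the thresholds
(meanlog = log T − σ·Φ⁻¹(1 − p) for upper-limit markers, analogously for
lower-limit ones; σ = 1.2 for CA 125, 0.5 for the protein markers — CA 125
spans orders of magnitude in serum, the carrier proteins are tighter).
CA 125 gets a menopause-specific location per class so its exceedance of
the menopause-specific cutoff equals the class rate in both strata, making
the marginal operating point independent of the menopause mix. The solved
rates are stored in `sim_params()$marker_positivity`.

Markers are independent within class by default, which is what keeps the
analytic calibration exact; a Gaussian-copula equicorrelation parameter
(`marker_correlation`) is available because real panels correlate, and
turning it on preserves the per-marker margins while raising the joint
3-of-5 exceedance. Deliberately not modelled: assay measurement error,
batch effects, verification bias, stage-dependent marker levels, and any
dependence of the clinician impression on the markers given class (the
impression is conditionally independent by construction). Passing tests on
generated cohorts therefore demonstrates correctness of the pipeline under
these stated assumptions, not performance of the rule on real patients —
in particular the generator cannot reproduce the empirical pattern of
higher panel sensitivity in early- than late-stage disease, which the
deterministic `reference_cohort()` carries instead.

## Numerical and degenerate-input choices

* Confusion cells are validated as non-negative integers; an empty table
  is an error, and metrics with zero denominators are `NA`.
* Subtype frequency ordering breaks count ties alphabetically, making the
  rendering deterministic.
* The composite "panel and/or clinician" test is always the per-patient
  logical OR, never marginal algebra.
* Tests and the pipeline treat a cohort with no malignant cases as valid
  except where a quantity is undefined (the stage distribution errors).
* Problem sizes: oracle-equivalence checks run at exhaustive small scale
  (all 32 vote patterns, all McNemar discordant splits with b + c ≤ 20,
  Fisher enumeration at n ≤ 60); round-trip reconstruction uses 1 000
  random tables with n ≤ 500; parameter-recovery uses one calibrated
  cohort of 100 000 patients with 3-standard-error bands, a size at which
  the generator runs in well under a second.

## Known discrepancies and limitations

Two printed values in the source material are arithmetically inconsistent
with their own tables and are treated as typographical: an early-stage
McNemar p printed as 0.0125 where the exact test on the printed cells
(b = 4, c = 0) gives 0.125, and a malignancy rate printed as 19.9% where
30/150 = 20.0%. The package reproduces 0.125 and 20.0. The thresholds are
kit-specific reference ranges, editable via `read_thresholds()` for other
kits; no threshold optimisation (ROC tuning) is provided, no confidence
intervals for the accuracy metrics, no multiple-testing correction for the
association rows, and no Fisher test beyond 2×2 — matching the scope of
the analysis the package reproduces.
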