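# miascreen

Preoperative triage of ovarian masses with a software-independent
multivariate index assay, plus the complete statistical machinery to
evaluate it as a screening test.

## The problem

Distinguishing benign from malignant ovarian masses before surgery is hard:
no single ultrasound feature or serum marker is reliable, and early referral
of likely cancers to an oncology surgeon improves survival. The commercial
five-marker multivariate index assay (OVA1/OvaCalc) combines CA 125,
beta-2 microglobulin, transferrin, apolipoprotein A1 and prealbumin
(transthyretin) into a proprietary 0–10 score — but the scoring software is
not available in many settings. `miascreen` implements the modified,
cutoff-based alternative designed for exactly that situation, together with
everything needed to evaluate it against surgical histopathology in a
cohort study. It is aimed at clinical researchers and biostatisticians
running (or re-analysing) diagnostic-accuracy studies of biomarker panels.

## The rule

Each marker is called positive against its laboratory reference range,
with strict inequalities (a value exactly at a limit is in range):

| Marker | Positive when | Threshold |
|---|---|---|
| CA 125 | above upper limit | 200 IU/L premenopausal / 35 IU/L postmenopausal |
| beta-2 microglobulin | above upper limit | 2.46 g/L |
| transferrin | below lower limit | 2.24 g/L |
| apolipoprotein A1 | below lower limit | 1.24 g/L |
| prealbumin | below lower limit | 0.216 g/L |

A mass is **high risk** when **at least 3 of the 5** calls are positive
(`mia_classify()`). A partial panel is an error, never a 3-of-4 vote.
Menopause follows the 12-month amenorrhoea rule, with age ≥ 50 deciding
only when the woman is unsure of her menses.

Around the rule the package provides, as plain functions:

* `confusion_table()`, `accuracy_metrics()` — sensitivity, specificity,
  PPV, NPV and total agreement against the histopathology gold standard,
  with undefined ratios reported as `NA`;
* `mcnemar_exact()` — the exact binomial McNemar test,
  `p = min(1, 2·P(Bin(b+c, ½) ≤ min(b,c)))`;
* `chi_square_test()`, `fisher_exact_2x2()`, `expected_counts()`,
  `select_test()` — risk-factor association with the ">20% of expected
  counts below 5" rule choosing between uncorrected Pearson chi-square and
  the two-sided Fisher exact test;
* `reconstruct_confusion()` — recovers the unique integer 2×2 cells from
  the summary statistics a paper prints (n, disease positives, test
  positives, agreement %);
* `generate_cohort()` / `sim_params()` — a class-conditional synthetic
  cohort generator calibrated so the panel operates near 70% sensitivity /
  96.7% specificity;
* `run_study()` — one command from a cohort CSV to the full set of study
  tables (associations, subtypes, positivity, validity, stage-stratified
  analyses, stage distribution), rendered as text, JSON and CSV by
  `write_report()`.

A thin command-line front end with `simulate`, `classify`, `evaluate`,
`associate`, `reconstruct` and `run` subcommands ships in `inst/cli/`.

## Worked example

Classify one postmenopausal patient:

```r
library(miascreen)
mia_classify(list(ca125 = 58, b2m = 3.1, transferrin = 1.9,
                  apoa1 = 1.1, prealbumin = 0.25), "postmenopausal")
#> MIA 3-of-5 vote: 4 of 5 markers positive -> HIGH risk of malignancy
#>   positive: ca125, b2m, transferrin, apoa1
```

Four markers are out of range (CA 125 is 58 IU/L, above the postmenopausal
35 IU/L cutoff), so the vote exceeds the 3-of-5 threshold and the mass is
flagged for oncology referral.

`reference_cohort()` is a deterministic synthetic reconstruction of a
published 150-woman evaluation cohort (30 malignant, 120 benign) from its
printed summary tables. Evaluating the panel on it:

```r
evaluate_test(classify_cohort(reference_cohort()), "mia_high_risk")
#> Sensitivity 70.0%  Specificity 96.7%  PPV 84.0%  NPV 92.8%  Agreement 91.3%
#> Exact McNemar vs gold standard: P = 0.267
```

21 of 30 cancers are caught, only 4 of 120 benign masses are falsely
flagged, and the exact McNemar test finds no significant asymmetry between
the panel's calls and histopathology. The same cells fall out of the
printed marginals alone:

```r
reconstruct_confusion(n_total = 150, n_disease_pos = 30,
                      n_test_pos = 25, agreement_pct = 91.3)
#>           histopathology
#> test       malignant benign
#>   positive        21      4
#>   negative         9    116
```

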