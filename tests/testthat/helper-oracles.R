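# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# exact two-sided McNemar by explicit binomial pmf summation
oracle_mcnemar <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  pmf <- choose(n, 0:n) / 2^n
  min(1, 2 * sum(pmf[seq_len(k + 1)]))
}

# two-sided Fisher p by enumeration of all 2x2 tables with the observed
# margins, using explicit binomial-coefficient arithmetic
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  pk <- function(k) choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  p_obs <- pk(m[1, 1])
  sum(vapply(lo:hi, function(k) {
    p <- pk(k)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# 3-of-5 vote by explicit pattern enumeration on a named positivity vector
oracle_vote <- function(calls) sum(calls) >= 3

# a random confusion table with grand total at most n_max
random_confusion_cells <- function(n_max = 500) {
  n <- sample(4:n_max, 1)
  cuts <- sort(sample(0:n, 3, replace = TRUE))
  c(tp = cuts[1], fp = cuts[2] - cuts[1], fn = cuts[3] - cuts[2],
    tn = n - cuts[3])
}

# panel values placed on the required side of each threshold for a given
# positivity pattern (bits ordered ca125, b2m, transferrin, apoa1, prealbumin)
panel_from_pattern <- function(bits, th = marker_thresholds(),
                               menopausal = "premenopausal") {
  ca_cut <- if (menopausal == "postmenopausal")
    th$ca125_postmenopausal_upper else th$ca125_premenopausal_upper
  list(
    ca125 = if (bits[1]) ca_cut * 2 else ca_cut / 2,
    b2m = if (bits[2]) th$b2m_upper + 1 else th$b2m_upper - 1,
    transferrin = if (bits[3]) th$transferrin_lower / 2 else th$transferrin_lower + 1,
    apoa1 = if (bits[4]) th$apoa1_lower / 2 else th$apoa1_lower + 0.5,
    prealbumin = if (bits[5]) th$prealbumin_lower / 2 else th$prealbumin_lower + 0.05
  )
}

# build a confusion_table from cells by expanding to paired calls, so tests
# exercise the counting path rather than any internal constructor
new_confusion_for_test <- function(tp, fp, fn, tn) {
  calls <- rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fp, fn, tn))
  truth <- rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fp, fn, tn))
  confusion_table(calls, truth)
}
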