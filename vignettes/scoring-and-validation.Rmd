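---
title: "Scoring and validating the AIIMS-Modified INDT-ASD instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating the AIIMS-Modified INDT-ASD instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indtasd)
```

## The scoring model

The AIIMS-Modified INDT-ASD instrument operationalizes the DSM-5
two-cluster model of autism spectrum disorder as 28 `yes`/`no`/`unsure`
questions in 7 subdomains — three social interaction/communication
clusters (A1a with 8 questions, A1b with 4, A1c with 3) and four
restricted/repetitive behaviour clusters (A2a with 7, A2b and A2c with 1
each, A2d with 4 sensory-symptom questions) — plus two mandatory Section B
items: onset in the early developmental period, and impairment of daily
functioning.

Every question is answered by two raters (caregiver interview and
investigator observation). Reconciliation is deterministic:

1. agreement (including both `unsure`) stands;
2. a lone `unsure` yields to the definite answer — precedence is *not*
   invoked, because `unsure` is only ever recorded when both raters are
   unsure;
3. a definite `yes`-vs-`no` conflict is settled by the rater the question
   names as taking precedence.

A reconciled answer is abnormal when it equals the question's
abnormal-response polarity; `unsure` is never abnormal and contributes 0
to the total score (scoring only defines abnormality for definite
answers; counting `unsure` as abnormal would inflate severity for the
least-informative records). The total score is the abnormal count, 0–28.
The diagnostic call requires all three A1 subdomains abnormal, at least 2
of the 4 A2 subdomains abnormal, and both Section B items — equivalently
at least 7 of the 9 criteria, with the qualification below.

### Design choices on points the instrument text leaves open

* **Within-subdomain thresholds.** The minimum number of abnormal
  questions that flags a subdomain is stored per subdomain in the
  instrument definition and defaults to 1 everywhere. The single-question
  subdomains (A2b, A2c) force a threshold of 1, and a uniform default is
  the least surprising choice; sites with the published instrument
  booklet can set the booklet's true per-subdomain rules in the YAML
  definition.
* **Polarity and precedence defaults.** The shipped definition sets every
  question's abnormal response to `no` and precedence to `investigator`.
  These are explicit, editable placeholders — the booklet's per-question
  rules are not derivable from the instrument's published description,
  and a visible uniform default beats a silent invention. Scoring
  behaviour is polarity-symmetric, so none of the package's structural
  results depend on this choice.
* **"7 of 9" versus the structural rule.** For arbitrary 7-subsets of the
  9 criteria the two formulations differ (e.g. 2 of 3 A1 clusters plus
  all A2 and both B items is 7 criteria but not a case). The structural
  rule is primary here; `criteria_met_count` is reported alongside, and
  the test suite verifies by exhaustive enumeration of all
  2^7 × 2^2 combinations that every positive call has at least 7
  criteria.
* **Severity band labels.** The validated cutoffs are ≥ 10 (ASD), ≥ 11
  (moderate, corresponding to CARS 34–36.5) and ≥ 14 (severe, CARS
  > 36.5). The instrument defines cutoffs, not disjoint bands; the
  non-overlapping labels `below_threshold` / `asd_mild` / `asd_moderate`
  / `asd_severe` are a reporting convention of this package, and the
  cutoffs are caller-configurable.
* **Missing answers.** Incomplete records are a hard error, never
  imputed: the instrument is administered in full, so a missing answer is
  a data-entry fault that should surface, not be smoothed over.

## The validation statistics

Accuracy measures are the standard 2×2 ratios; all four confidence
intervals are Clopper–Pearson exact (beta-quantile) intervals, the method
that reproduces all eight published CI bounds of the instrument's
validation table. Percentages are displayed half-up at two decimals
(one decimal in the severity cross-tab), matching clinical reporting
practice.

The ROC positive rule is `score >= cutoff` — the direction in which all
of the instrument's cutoffs are phrased. One ROC point is produced per
distinct observed score plus a sentinel at `+Inf`; the AUC is the
trapezoidal area, which equals the tie-corrected pairwise concordance
probability (verified against a brute-force O(n²) oracle in the tests).
The Youden-optimal cutoff maximizes J = sensitivity + specificity − 1,
with ties broken toward the smallest cutoff (deterministic, and the
sensitivity-favoring choice for a diagnostic instrument). Cohen's kappa
is unweighted — the inter-rater use case is a binary diagnosis, so
weighting is moot. Cronbach's alpha uses the usual variance
decomposition with per-item alpha-if-deleted values.

The comparison population for severity-cutoff ROCs is deliberately
caller-configurable (severe-vs-rest, severe-vs-other-ASD, ...):
`roc_curve()` takes whatever label vector the analyst passes, because the
instrument's validated severity cutoffs do not pin down a single
comparison population.

## What the synthetic cohort emulates

`cohort_params()` defaults encode the structure of the instrument's
published validation cohort:

| Parameter | Default | Source |
|---|---|---|
| `n` | 225 | enrolled cohort size |
| `prevalence` | 128/225 (56.9%) | reference-positive fraction |
| `band_mix_pos` | (11, 37, 80)/128 | CARS bands among ASD-positive |
| `band_mix_neg` | (95, 2, 0)/97 | CARS bands among ASD-negative |
| `dq_mix` | (115, 64, 33, 8, 2, 3)/225 | developmental-quotient bands |
| `p_abnormal_pos` | 0.80 per question | package choice (see below) |
| `p_abnormal_neg` | 0.25 per question | package choice |
| `b_item_rates_pos` | (0.995, 0.995) | package choice |
| `b_item_rates_neg` | (0.70, 0.50) | package choice |
| `rater_disagreement` | 0.05 | package choice |
| `unsure_rate` | 0.02 | package choice |
| `severity_slope` | 0 | off unless studying severity cutoffs |

Class-conditional mixtures use the exact published counts rather than
their rounded percentages. Item-level response distributions and
rater-noise rates were never published, so those defaults are fixed
package choices, made once analytically: with a threshold of 1, a
subdomain of *k* questions is abnormal with probability 1 − (1 − p)^k,
so p = 0.8 per question gives a decision-rule call probability of about
0.97 for the positive class and p = 0.25 gives about 0.09 for the
negative class — near the instrument's published operating point
(sensitivity 98.4%, specificity 91.7%) before rater noise. The B-item
rates reflect that a referred non-ASD population (largely global
developmental delay) frequently shows early-onset symptoms (0.70) and
functional impairment (0.50), while nearly every ASD-positive child
shows both.

The generative model per child: latent class ~ Bernoulli(prevalence);
CARS band ~ class-conditional categorical, with the score uniform within
the band's support (non-autistic [15, 30), mild-moderate [30, 36.5],
severe (36.5, 60] — uniform is the minimal assumption given only band
counts); per-question latent abnormality ~ Bernoulli at the subdomain's
class-conditional probability, optionally modulated logistically in
centered CARS (`severity_slope`, default 0: the real score–severity
coupling strength is unknown, so it is off unless a severity analysis
turns it on); the abnormality maps through the question's polarity to a
true response; each rater reports that response independently flipped
with probability `rater_disagreement` and then replaced by `unsure` with
probability `unsure_rate`; Section B items ~ class-conditional
Bernoulli. DQ is generated for report parity only — scoring never reads
it.

All randomness flows from one root seed through per-child substreams
(per-child seeds drawn once from the root), so a cohort is byte-identical
under the same parameters and its content does not depend on iteration
order.

**What this does and does not show.** The simulator reproduces the
cohort's marginal structure and a plausible noise process; it is not a
clinical-realism model of autism symptomatology. Questions within a
subdomain are conditionally independent given class (real symptom
clusters correlate), there are no age or sex effects on items, no
missing-data mechanism, and the score–CARS joint distribution is not
calibrated to the published correlation (r = 0.76), which cannot be
pinned down without the original per-child data. Passing tests therefore
demonstrate the correctness of the scoring and validation machinery
under a known generative model — not the field performance of the
instrument.

## Numerical choices

* Clopper–Pearson bounds come from `qbeta`; the boundary cases x = 0 and
  x = n are returned exactly as 0 and 1.
* Display rounding is half away from zero (`round_half_up`), because
  R's banker's rounding differs from how clinical tables are printed;
  all statistics are computed and returned at full precision and only
  rounded for display.
* Degenerate inputs fail loudly by design: zero-denominator accuracy
  measures, single-class ROC labels, constant raters (kappa),
  zero-variance totals (alpha) and zero-variance inputs (correlation)
  are errors naming the undefined statistic, not `NA`s.
* CARS scores outside the instrument's 15–60 range are banded anyway
  with a warning; children with *missing* CARS are excluded from the
  cross-tab with a logged count.

## Problem sizes in the test suite

The suite exercises the pipeline at the sizes a laptop run completes in
seconds: exhaustive enumeration of the 512 decision-rule input
combinations; 200 random ROC instances against the brute-force
concordance oracle; exact-interval coverage at 2,000 replicates over
p ∈ {0.1, 0.5, 0.9} × n ∈ {20, 100}; parameter recovery through the full
pipeline at n = 5,000 against an exact enumeration of the per-class call
probability; marginal recovery at n = 20,000; and an end-to-end CLI run
at the study's own n = 225.

## Known limitations

* The shipped instrument definition carries placeholder prompts and
  uniform polarity/precedence/threshold defaults; faithful per-question
  behaviour requires transcribing the published booklet into the YAML
  definition.
* Reliability coefficients measured on the real pilot (kappa 0.95, alpha
  0.92) and cohort-level results (AUC 0.98/0.93/0.89, r = 0.76) depend on
  the original data and are not reproduced here; the package reproduces
  every statistic that is a deterministic function of published counts,
  and provides the estimators for use on real data.
* No DeLong AUC variance, paired ROC tests, multi-rater agreement beyond
  two raters, or IRT modelling.
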