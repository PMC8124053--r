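---
title: "Methods: the NEP score, threshold evaluation and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NEP score, threshold evaluation and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nepscore)
```

## The score model

The NEP score is an additive point system for stage IV well-differentiated
entero-pancreatic neuroendocrine neoplasms. Six components contribute:
age band at diagnosis (0/28/58 points), primary site (ileum 0, pancreas
59), primary-tumor surgery (resected 0, not resected 100), functional
status (hormone-related symptoms 32, none 0), Ki67 band (0/12/57) and
metastasis timing (synchronous 0, metachronous after more than 24 months
38, metachronous within 24 months 72). Two scores are derived: **NEP-D**,
the sum of the five components available at diagnosis, and **NEP-T**,
which adds the timing component and is therefore only computable once
follow-up has revealed whether and when metachronous metastases appeared.
Their difference, **Delta-NEP**, is exactly the timing component and
takes only the values 0, 38 or 72. Attainable ranges are 0–306 for NEP-D
and 0–378 for NEP-T. Risk classes partition the score range at 70 and
199: low (≤ 70), intermediate (71–198), high (≥ 199).

Three band boundaries required a decision because the published bands do
not cover the real line:

* **Age exactly 45.** The printed age bands are "< 45" and "46–65",
  leaving 45 unassigned. We implement the low band as *age < 46*, so 45
  scores 0 — the reading consistent with contiguous integer-age bands.
  The whole point table is a run-time configuration
  (`nep_score_table()`, YAML round-trip via `read_score_table()`), so
  a user who prefers the other reading can supply it without code change.
* **Non-integer Ki67.** The bands "0–2", "3–20", "> 20" are interpreted
  on the continuous percentage as [0, 3), [3, 20], (20, 100], preserving
  the WHO G1 boundary of Ki67 < 3 %: a Ki67 of 2.5 % scores 0.
* **Primary sites beyond ileum and pancreas** are rejected by default —
  the score was derived on strictly ileal/pancreatic cohorts — but a
  site-alias table (e.g. jejunum → ileum) can be configured explicitly.

All point arithmetic is exact integer arithmetic; no fractional points
exist.

Eligibility mirrors the score's target population: stage IV, well
differentiated, entero-pancreatic primary, follow-up over 24 months.
`check_eligibility()` returns the failed criteria per record rather than
a bare flag, and `read_cohort()` likewise collects per-row validation
issues instead of silently dropping rows.

## Threshold evaluation

A cutoff is evaluated with the orientation *score ≥ threshold predicts
death at end of follow-up*. From the resulting 2×2 table,
`diagnostics()` reports sensitivity, specificity, PPV, NPV, accuracy and
Youden's J as raw proportions; display rounding goes through
`as_percent()`, which rounds half *up* (0.5 → 1) to match clinical
reporting conventions rather than R's round-to-even. A metric whose
denominator is zero is `NA` — an explicit undefined marker — never a
silent 0/0.

"The best compromise between sensitivity and specificity", the phrase
under which the published cutoffs (145 for NEP-T; 90 and 116 for NEP-D)
were chosen, is not an algorithm. `scan_thresholds()` therefore evaluates
*every* distinct observed score (plus a +∞ sentinel) and selects a best
cutoff under an explicit, configurable policy: maximal Youden's J
(default; ties broken by higher specificity, then lower threshold),
minimal |sensitivity − specificity|, or maximal accuracy. The full scan
table is always returned so alternative policies can be audited. Without
patient-level data the published cutoffs cannot be re-derived; they are
treated as fixed inputs.

Group association at a cutoff uses Pearson's chi-square *without*
continuity correction as the primary statistic (the source analyses do
not state a correction); the Yates-corrected value is reported alongside.
Mean comparisons default to the unpaired Welch t-test. The original
methods description mentions a *paired* Student's t-test "among groups",
but alive-vs-dead groups of 15 and 12 cannot be paired; we reserve
pairing for within-patient comparisons (NEP-D vs NEP-T, where it is the
correct test) and expose both modes.

### Reconstructing published 2×2 tables

The published accuracy metrics come with enough margins — cohort size 27,
12 deaths, percent dead above and below the cutoff — to recover the
underlying table by exhaustive enumeration. `reconstruct_confusion()`
ranks all feasible nonnegative-integer tables by the absolute discrepancy
between their one-decimal group death percentages and the printed ones.
For NEP-T ≥ 145 ("80 %" / "23.5 %") exactly one table has discrepancy
zero: (tp, fp, fn, tn) = (8, 2, 4, 13), and it reproduces every printed
metric (sensitivity 67 %, specificity 86.7 %, PPV 80 %, NPV 76.5 %,
accuracy 77.8 %). For NEP-D the printed group percentages cannot be hit
exactly by any integer table — 28.5 % vs the attainable 4/14 = 28.6 %,
29.5 % vs 5/17 = 29.4 % — which we treat as rounding noise in the source;
the minimum-discrepancy table is unique in both cases and reproduces the
printed sensitivity/specificity/PPV/NPV. One published figure is
internally inconsistent: an accuracy of "82 %" is printed for NEP-D ≥ 90,
but the table implied by that cutoff's own sensitivity/specificity/PPV/
NPV gives 18/27 ≈ 66.7 %. We flag it here and exclude it from checks.

## Survival statistics

`km_fit()` wraps the product-limit estimator
(`survival::survfit`) with events-before-censorings tie handling; the
test suite verifies it against an independently coded brute-force
product-limit walk on every event/censor pattern of cohorts up to size 6.

`stratify_survival()` reports, per stratum, the arithmetic mean of
*observed follow-up time* with its SEM — labelled "mean OS" for
comparability with the clinical literature this score comes from, where
group means over cohorts including censored patients are reported as mean
overall survival. For a censored patient this conflates follow-up
duration with survival, so the KM median is reported alongside and the
log-rank test (not the mean-OS t-test) is the principled comparison; both
are returned. Time origin is diagnosis, the unit is months throughout.

Five-year status uses a 60.0-month boundary: follow-up reaching 60 months
(alive at exactly 60, or death at or after 60) counts as alive at five
years; death before 60 counts as not alive; censoring before 60 makes the
patient not evaluable, and that count is reported rather than hidden.

## The cohort simulator

`simulate_cohort()` exists so every downstream analysis is testable
without the (unavailable) patient-level data. It emulates the study
conditions:

* **Marginals** (defaults of `sim_config()`): 27 patients; 17/27 male;
  14/27 pancreatic; 21/27 resected; 9/27 functional; Ki67 bands
  17/27, 7/27, 3/27; 12/27 synchronous. The published table gives only
  the 15-patient metachronous *total*; the default splits it 50/50
  between the ≤ 24- and > 24-month bands, an arbitrary choice exposed as
  a parameter.
* **Age**: normal, mean 60, SD 15 years, truncated to 26–84 (published
  mean 60.2, median 64, range 26–84).
* **Within-band Ki67**: uniform inside the band. For the > 20 % band the
  uniform reaches to 100 %, which is generous for well-differentiated
  tumors (real WD G3 Ki67 rarely exceeds ~55 %); only the band, not the
  value, enters the score, so this does not affect any scored quantity.
* **Survival**: exponential with per-month rate `exp(a + b · NEP_T)`
  (a Weibull shape parameter is exposed; shape 1 is the default for
  closed-form checkability). Censoring — end of follow-up while alive —
  is uniform on 25–120 months. The defaults `a = −5.5`, `b = 0.01` per
  NEP-T point were fixed by simulating 20 000 patients under the default
  marginals: they give ~44.6 % overall mortality and ~47.4 months mean
  survival among the deceased, matching the study's 44.4 % and 47.5
  months. `b = 0.01` corresponds to a hazard ratio of `exp(1) ≈ 2.7` per
  100 score points.
* **Eligibility**: observed times at or below 24 months are resampled
  (whole-patient redraw), so default cohorts always satisfy the
  follow-up rule.

Covariates are drawn independently — the source reports only marginals,
not joint structure — so the simulator does not reproduce real-world
correlations such as pancreatic primaries tending to higher Ki67. Passing
tests on simulated cohorts therefore demonstrates the *pipeline's*
correctness and calibration, not clinical validity on real joint
distributions.

Two properties of the selection step deserve note. First, at `b > 0` the
eligibility resampling is a score-dependent selection: high-score
patients die early more often and are redrawn, which shifts the realized
covariate marginals away from their targets by several points (observed
up to ~7 points at n = 10 000). The marginal-concentration check in
`marginal_check()` is therefore calibrated against the *unselected*
sampler (`min_followup = 0`); with selection on, deviations of this size
are expected behavior, not bugs. Second, likelihood-based parameter
recovery must also use `min_followup = 0`, because the selection
truncates the exponential law and would bias a naive likelihood.

### Calibration and parameter recovery

`fit_hazard_link()` maximizes the censored exponential log likelihood
`Σ dead·(a + b·s) − Σ exp(a + b·s)·t` over a 61×61 grid with three zoom
passes (final grid step ≈ 6·10⁻⁴ in `a`, 6·10⁻⁶ in `b`, well below the
statistical error at the problem sizes used). The test suite cross-checks
it against the equivalent Poisson regression with log-time offset, and
verifies on a 10 000-patient cohort that both parameters are recovered
within 10 % (observed errors are ~1–4 %).

Null calibration uses `b = 0` with n = 200 per replicate — large enough
for the chi-square asymptotics the test relies on; this checks the
*test's* calibration, not cohort emulation — and finds the rejection rate
at the nominal 5 % level within 5 % ± 2 % over 2 000 replicates.

## Problem sizes and numerical choices

The automated checks run at sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances: all 216 covariate-band combinations
against an independent lookup; 1 000 random confusion-matrix recounts;
exhaustive product-limit enumeration to cohort size 6; 2 000 null
replicates of n = 200; one 10 000-patient recovery fit; 500 replicates of
n = 100 for the stratified-survival monotonicity property. That last size
matters: at the study's own n = 27 the probability that the high-score
stratum shows the lower *mean observed time* in a single draw is only
about 86 %, because censoring noise enters the mean; the hazard ordering
itself is deterministic in the generator, and at n = 100 the Monte-Carlo
probability exceeds 95 %. This is a useful reminder of how little a
27-patient cohort constrains mean-OS comparisons.

Percent formatting follows the source's two precisions: integer percents
for the cohort-features summary, one decimal for threshold metrics; raw
proportions are always retained in the returned tibbles.

## Known limitations

* The score weights themselves are taken as given; re-deriving them from
  survival regression is out of scope.
* No Cox regression, multivariable adjustment or competing-risk
  machinery: the analyses mirrored here are univariate.
* The simulator's covariate independence and exponential hazard are
  simplifications; both are parameterized (correlation could be layered
  on via the configuration, the Weibull shape is exposed) but the
  defaults make no claim of biological realism beyond the matched
  marginals and mortality.
* Bootstrap confidence intervals and ROC/AUC summaries beyond the
  threshold scan are deliberately absent.
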