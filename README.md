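# nepscore

Prognostic scoring and survival stratification for stage IV
well-differentiated (WD) entero-pancreatic neuroendocrine neoplasms (NEN).

Stage IV WD NEN of the ileum and pancreas range from indolent to rapidly
fatal, and grade and stage alone separate those courses poorly. The NEP
score condenses six routinely available characteristics into a single
point total; this package is for clinical researchers who want to compute
it on their own cohorts, evaluate threshold rules against survival, and
stress-test the whole pipeline on simulated data.

## The score

A patient's points are summed over six components:

| Component            | Bands                                     | Points       |
|----------------------|-------------------------------------------|--------------|
| Age at diagnosis     | < 46 / 46–65 / > 65 years                 | 0 / 28 / 58  |
| Primary tumor site   | ileum / pancreas                          | 0 / 59       |
| Primary resected     | yes / no                                  | 0 / 100      |
| Functional (hormone-secreting) | yes / no                        | 32 / 0       |
| Ki67 index           | 0–2 % / 3–20 % / > 20 %                   | 0 / 12 / 57  |
| Metastasis timing    | synchronous / metachronous > 24 mo / ≤ 24 mo | 0 / 38 / 72 |

Three derived quantities:

* **NEP-T** — the full sum, computable only at the end of follow-up
  because it includes the metastasis-timing component;
* **NEP-D** — the diagnosis-time score: the five components known at
  diagnosis, timing excluded;
* **Delta-NEP = NEP-T − NEP-D** — the timing component alone, a measure of
  metachronous metastasis development.

Risk classes partition the score range: low ≤ 70, intermediate 71–198,
high ≥ 199.

Around the score the package provides threshold evaluation (confusion
matrices, sensitivity/specificity/PPV/NPV/accuracy, Youden-J threshold
scans, chi-square association tests), Kaplan–Meier survival curves with
log-rank comparisons and five-year survival counts for score-defined
strata, cohort CSV validation and summary tables, reconstruction of
published 2×2 tables from cohort margins, and a synthetic-cohort
simulator with a score-linked exponential hazard.

## Worked example

```r
library(nepscore)

cohort <- simulate_cohort(sim_config(), seed = 42)  # 27 synthetic patients
scored <- nep_score(cohort)
scored[1:4, c("patient_id", "nep_d", "nep_t", "delta_nep", "risk_class_t")]
#>   patient_id nep_d nep_t delta_nep risk_class_t
#> 1 P001          60   132        72 intermediate
#> 2 P002          87    87         0 intermediate
#> 3 P003          58   130        72 intermediate
#> 4 P004          12    12         0 low
```

Patient P001 scores 60 at diagnosis (age band 28 + functional 32) and
gains 72 timing points from metastases that appeared within 24 months,
ending follow-up at NEP-T 132 — intermediate risk. P004 has none of the
adverse features and stays low risk.

```r
overall_mortality(scored)
#>   n_dead n_total mortality_pct
#> 1      9      27          33.3

stratify_survival(scored, 116, score = "nep_d")
#> Survival stratified at nep_d >= 116
#>   stratum          n n_dead p_dead mean_os sem_os km_median
#> 1 nep_d < 116     23      8  0.348    61.2   6.36      108.
#> 2 nep_d >= 116     4      1  0.25     54.8  13.3        NA
#> Log-rank chi2 = 0.007, p = 0.9357
```

Nine of the 27 simulated patients died (33.3 % mortality). At the NEP-D
cutoff of 116 this particular draw puts only four patients in the high
stratum; their mean observed survival is shorter (54.8 vs 61.2 months)
but with n = 27 the log-rank test is far from significance — exactly the
small-sample behavior the simulator exists to expose.

Published 2×2 tables can be reconstructed from their printed margins; for
a 27-patient cohort with 12 deaths where 80 % of high-score and 23.5 % of
low-score patients died, the unique consistent table and its metrics are:

```r
diagnostics(reconstruct_confusion(27, 12, 80, 23.5)[1, ])
#>   tp fp fn tn ... sensitivity specificity  ppv   npv accuracy
#> 1  8  2  4 13 ...       0.667       0.867  0.8 0.765    0.778
```

A command-line front end for shell use lives at
`system.file("cli/nepscore.R", package = "nepscore")` with subcommands
`score`, `summarize`, `evaluate`, `scan`, `survival`, `report` and
`simulate`.

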