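# adherecut

Evidence-based thresholds for medication adherence. Given claims-style
tables — drug dispensations, hospital stays, outcome/vital events, baseline
covariates — `adherecut` builds a new-user cohort, computes each patient's
proportion of days covered (PDC) over outcome-anchored follow-up windows,
and estimates the PDC threshold that best separates patients by risk of a
time-to-event outcome. It is aimed at pharmacoepidemiologists who want to
replace the conventional "PDC ≥ 0.80 = adherent" rule with a cut estimated
from their own cohort and outcome.

Three estimators are implemented:

- **Contal–O'Quigley**: the maximally selected log-rank statistic. For each
  candidate `c`, the two-group log-rank numerator
  `U(c) = Σ_t [d_low(t) − d(t)·n_low(t)/n(t)]` is computed over the ordered
  event times with the low group defined by `PDC < c`; the threshold
  maximizes `|U(c)|`, standardized as `q = max|U| / (s√(D−1))` with the
  variance constant `s² = (1/(D−1)) Σ_i (1 − Σ_{j≤i} 1/(D−j+1))²` over the
  `D` event times and tail approximation `p ≈ 2·exp(−2q²)`.
- **Youden's J**: maximizes `J = Sn + Sp − 1` for the classifier
  "`PDC < c` predicts event".
- **Minimum distance**: minimizes `d = √[(1−Sn)² + (1−Sp)²]`, the distance
  from the ROC point to perfect classification.

Candidate thresholds are then adjudicated with adjusted Cox
proportional-hazards models (age, sex, seven comorbidities, and — for the
ACS/stroke outcome — hospitalization during follow-up), compared by
`ΔAIC = AIC − min AIC` with Burnham–Anderson support categories; thresholds
with `ΔAIC < 4` define the retained range. PDC handles pooled drug-class
switching, carry-in supply, an optional stockpiling (carryover) mode, and
hospital-day subtraction from both numerator and denominator.

A synthetic-claims generator with a known true threshold τ\* and hazard
ratio HR\* makes the entire chain testable without access to administrative
data; its truth table is never read by the analysis code.

## Worked example

Generate a synthetic study whose true threshold is 0.50 with a hazard ratio
of 2, run the chain for the ACS/stroke outcome, and adjudicate:

```r
library(adherecut)

study  <- generate_study(sim_config(n_patients = 5000, seed = 42,
                                    tau_star = 0.5, hr_star = 2))
cfg    <- run_config(seed = 42)
cohort <- build_cohort(study, cfg)
cohort_summary(cohort)
#>                total             included INSUFFICIENT_HISTORY
#>                 5000                 4610                   76
#>         NOT_NEW_USER          PRIOR_EVENT       SHORT_FOLLOWUP
#>                    0                   91                  223

rows <- build_analysis_table(cohort, study, "ACS_STROKE", cfg)
grid <- make_candidate_grid(rows$pdc, "resolution", 0.01, 0.05)
estimate_cutpoints(rows, grid)$results
#>            method threshold statistic
#> 1 CONTAL_OQUIGLEY      0.50 1.8789194
#> 2          YOUDEN      0.50 0.1252176
#> 3    MIN_DISTANCE      0.78 0.6428955

cmp <- compare_thresholds(rows, c(0.40, 0.45, 0.50, 0.55, 0.60, 0.80),
                          default_covariates("ACS_STROKE", cfg))
cmp
#>   threshold    hr ci_low ci_high  aic delta_aic             support
#> 1      0.40 1.812  1.351   2.431 3329    2.3604 retained-borderline
#> 2      0.45 1.847  1.383   2.467 3327    0.8975         substantial
#> 3      0.50 1.856  1.396   2.469 3327    0.0000         substantial
#> 4      0.55 1.685  1.267   2.241 3331    4.7482   considerably-less
#> 5      0.60 1.582  1.192   2.100 3334    7.2733              little
#> 6      0.80 1.381  1.045   1.827 3338   11.7512                none
retain_threshold_range(cmp)$range
#> [1] 0.4 0.5
```

The scan and Youden's J both land on the true threshold 0.50; the adjusted
model dichotomized there has the lowest AIC, and the retained range
(ΔAIC < 4) is 0.40–0.50. Note the attenuation pattern: dichotomizing at the
conventional 0.80 — far from the true cut — drags the estimated hazard
ratio from 1.86 down to 1.38 and earns "no support" from the AIC
comparison. `run_full_study()` repeats this chain for all three outcomes
(ACS/stroke, all-cause and cardiovascular mortality) overall and within age
strata, and `write_report()` emits a JSON report plus per-table CSVs. A thin
command-line wrapper with `simulate` / `cohort` / `pdc` / `cutpoints` /
`compare` / `run` subcommands lives in `inst/scripts/adherecut.R`.

The methods vignette (`vignettes/adherence-thresholds.Rmd`) documents the
model, the window anchoring, the generator's design, and known limitations.

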