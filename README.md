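# hivstadhere

Adherence classification and incidence analysis for longitudinal HIV
self-testing (HIVST) event logs.

Mobile HIVST services produce per-participant testing histories: a baseline
questionnaire and a dated sequence of test results with condom-use
responses. Public-health guidance for sexually active MSM recommends an HIV
test every 3 months, so the scientific questions are: who actually adheres
to that schedule, what predicts adherence, and does adherence pay off in
earlier case detection and safer behavior? This package implements the full
analysis chain for such data, for epidemiologists and biostatisticians
working with self-testing event logs — plus a synthetic cohort generator
with known ground truth so every stage can be validated without any study
data.

## What it computes

**Eligibility cascade and adherence.** Registered participants are filtered
in fixed order: never tested; positive at the first test; a single negative
test within 100 days of the study endpoint (adherence not yet judgeable).
An included participant is *adherent* iff

1. every gap between adjacent tests is ≤ 100 days (inclusive), and
2. the last test lies ≤ 100 days before the study endpoint — waived when
   the last test is positive, since a confirmed seroconverter needs no
   further tests.

A test is an *adhering test* when its gap from the previous test is
≤ 100 days; first tests never count, so each participant contributes
`n_tests − 1` eligible intervals.

**Incidence.** Seroconversion is dated at the floored midpoint of the last
negative and first positive test. Follow-up runs from the first test to the
seroconversion date (converters) or last test (censored); person-years are
day counts / 365.25. Rates are `100·k/T` with exact Poisson intervals in
two chi-square quantile dialects:

- `garwood` (textbook): event-scale bounds `[½χ²(α/2, 2k), ½χ²(1−α/2, 2k+2)]`;
- `paper`: the same quantiles with the degrees of freedom swapped — the
  dialect that reproduces the published intervals this package's reference
  tables use. It is strictly contained in the Garwood interval.

**Group comparisons and effects.** Uncorrected Pearson chi-square tests,
Wald odds ratios from 2×2 counts, logistic regression (IRLS, polished to
max |score| < 1e−8 so it agrees with closed-form 2×2 odds ratios to
machine-level precision), Cox proportional-hazards fits (Breslow/Efron
ties), multiple imputation of missing categorical covariates stratified by
adherence label, and Rubin pooling.

**Behavior change.** Condom-use transitions from the first to the kth test
are classified Better / Worse / Other from a total 16-pair map of the
(Never, Ever, Consistent, Uncertain) categories, and compared between
adherence groups.

## Worked example

```r
library(hivstadhere)

co  <- simulate_cohort(sim_config(n_participants = 1500, seed = 2024))
rep <- run_pipeline(co, run_config(seed = 1))
print(rep)
#> <hivst report>
#> <adherence summary>
#>   registered 1500 = no-test 0 + baseline-positive 76 + indeterminate 345 + included 1079
#>   adherent 161 / 1079 (14.92%)
#>   adhering tests 448 / 747 intervals (59.97%)
#>   incidence (paper dialect):
#>     total:       9.37 per 100 PY (6.15-13.78) [k=21, T=224.15, paper]
#>     adherent:    20.23 per 100 PY (10.78-35.43) [k=9, T=44.49, paper]
#>     nonadherent: 6.68 per 100 PY (3.85-10.96) [k=12, T=179.66, paper]
```

The cascade line is the study-profile partition (registered = excluded +
included; included = adherent + nonadherent). The adherent group's higher
rate reflects the generator's archetype-specific hazards (0.171 vs 0.048
per person-year); the Cox fit on the same report gives

```r
print(rep$table3$cox)
#> <Cox fit> ties = breslow
#>   adherenceadherent            HR 3.65 (1.51-8.85) p=0.00414
```

Individual estimators work directly from printed aggregate inputs:

```r
incidence_rate(8, 46.77, dialect = "paper")
#> 17.10 per 100 PY (8.80-30.84) [k=8, T=46.77, paper]
incidence_rate(8, 46.77, dialect = "garwood")
#> 17.10 per 100 PY (7.38-33.70) [k=8, T=46.77, garwood]
odds_ratio_wald(26, 129, 55, 937)
#> OR 3.43 (2.08-5.67), p = 1.42e-06
pearson_chi_square(rbind(c(123, 1172), c(8, 12)))
#> chi-square = 20.429, df = 1, p = 6.19e-06
```

File-based cohorts use `read_cohort(participants.csv, events.csv, window)`;
the column schema and category levels are documented in
`inst/extdata/data_dictionary.csv`, and a fully hand-enumerated
6-participant example ships as `inst/extdata/fixture_*.csv` with its answer
sheet in `fixture_answers.json`.

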