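---
title: "Methods: adherence classification, incidence estimation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adherence classification, incidence estimation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivstadhere)
```

This vignette documents the statistical procedures the package implements,
the modelling assumptions behind the synthetic cohort generator, and the
numerical and design choices that were genuinely open — with the reasoning
that fixed them.

## The adherence model

The unit of observation is a participant's dated sequence of HIV self-test
events inside an analysis window (default 2017-07-01 to 2018-06-30).
Classification is a two-stage procedure.

**Eligibility cascade**, applied in fixed order: (1) registered but never
tested; (2) HIV-positive at the first test — already infected at entry, so
testing adherence is undefined; (3) exactly one negative test within the
interval threshold of the endpoint — such a participant may yet take a
timely second test, so adherence is indeterminate. Everyone else is
included. The fixed order makes the cascade counts a partition of the
registered cohort, which `run_pipeline()` checks and logs.

**Two-criterion classification** of included participants: all inter-test
gaps ≤ `threshold_days` *and* last test within `threshold_days` of the
endpoint, the second criterion waived when the last test is positive.
`threshold_days` defaults to 100 — the 3-month recommended testing interval
for sexually active MSM plus slack for postal delays — and is a parameter
so the rule can be stress-tested at other values; classification is
monotone in it (raising the threshold never demotes anyone), which the test
suite verifies by property.

Three boundary decisions were open and are resolved as follows:

- **Inclusiveness.** Both criteria and the adhering-test rule treat a gap
  of exactly 100 days as compliant. The source wording for each rule
  carries an explicit "including 100 days"/"less than or equal"
  parenthetical, which governs.
- **The single-test exclusion window** is taken inclusive
  (`endpoint − date ≤ threshold` ⇒ excluded) so that the exclusion rule is
  the exact complement of criterion 2: no participant can be excluded as
  indeterminate yet classify adherent, or vice versa, at any threshold. A
  strict-window variant is available (`inclusive_single_test = FALSE`)
  because the original cohort's convention is not decidable; the inclusive
  default is the internally consistent one.
- **Dirty sequences.** A negative test after a positive one is a
  validation-report violation, not an ingestion error; if such data are
  forced through, classification uses dates only and the waiver keys off
  the *final* event's result, keeping behavior deterministic.

Interval arithmetic is whole calendar days on ISO dates; two tests by one
participant on one date are rejected at ingestion (a mailing-based service
makes genuine same-day duplicates implausible, and silent tie-breaking
would corrupt gap counts).

## Incidence and hazards

Seroconversion is dated at the midpoint of the last negative and first
positive test, flooring the half day so exits stay calendar dates; the
sub-day difference is invisible at two-decimal person-years. Non-converters
are censored at their **last test**, not the study endpoint: exposure after
the last observation is unverifiable, and the reference tables' implied
mean follow-up supports this convention. Person-years divide day counts by
365.25.

Rates are `100·k/T` with exact Poisson intervals from chi-square quantiles.
Two dialects ship:

- `garwood` — lower `½χ²(α/2, 2k)`, upper `½χ²(1−α/2, 2k+2)` on the event
  scale; the textbook-exact interval whose ≥ nominal coverage the
  acceptance suite verifies empirically over 10,000 simulated draws.
- `paper` — the same quantiles with the degrees of freedom swapped. This
  is the dialect that reproduces, to the printed two decimals, all six
  interval bounds of the reference incidence table this package's tests
  pin; it is strictly contained in the Garwood interval for every `k`
  (more df raises the lower quantile, fewer df lowers the upper one).
  `incidence_rate()` defaults to it for reproduction; `garwood` is the
  recommended interval for new analyses.

All normal quantiles use the exact value (`qnorm(0.975)` ≈ 1.959964), not
1.96; the printed intervals reproduce only under the exact quantile.

`cox_fit()` maximizes the Cox partial likelihood through the `survival`
engine with Breslow tie handling by default — the default of the
statistical suite the original analysis names, hence the more plausible
reproduction — with Efron available. Its score test at β = 0 equals the
logrank statistic on tie-free two-group data, which the suite checks
against a hand-rolled logrank implementation. Non-convergence and monotone
likelihood (separation) abort with diagnostics rather than emitting
estimates.

## Contingency statistics, logistic models, imputation

Pearson chi-square tests carry **no continuity correction** by default:
the pinned reference statistics (e.g. 20.429 on the seroconversion 2×2)
match uncorrected Pearson; Yates is a flag. Zero-margin tables error,
naming the degenerate row or column.

Wald odds ratios use `OR = ad/bc` with log-scale
`se = √(1/a + 1/b + 1/c + 1/d)`; a zero cell errors unless the
Haldane–Anscombe `+0.5` flag is set, and corrected results are marked.
Reference levels are the first-listed dictionary categories (married;
junior high or below; ≤ 18; insertive only; offline venues; 0 partners; no;
2 tests or below) — the rows that carry OR 1.00 in the reference tables.

`logistic_fit()` runs IRLS via `glm` and then polishes with explicit Newton
steps until max |score| < 1e−8, evaluating the information-based standard
errors at the maximizer itself; this is what makes univariate fits agree
with closed-form 2×2 odds ratios to 1e−8, a dual-route check the
acceptance suite runs on 1,000 random tables. The "adjusted" model includes
every dictionary covariate plus the test-count category simultaneously;
alternative adjustment sets are first-class configuration
(`run_config(adjustment_sets = ...)`) to support sensitivity analyses that
vary the adjustment variables.

Missing values in the three imputable covariates (age group, marital
status, age of first anal sex — the variables with < 10% missingness) are
multiply imputed by a stratified hot-deck: each missing value is drawn from
the variable's observed distribution *conditional on the adherence label*.
The original analysis names no imputation engine; conditioning on the
outcome label is the simplest mechanism that preserves the
covariate–outcome association the pooled estimates care about, and the
mechanism is deliberately swappable. `m` defaults to 10. Pooling follows
Rubin's rules with the classic large-sample degrees of freedom
`(m−1)(1 + W̄/((1+1/m)B))²`.

## Behavior-change taxonomy

The 16 ordered pairs of (Never, Ever, Consistent, Uncertain) map totally
onto Better / Worse / Other: Better is any move up the protection ordering
plus maintained-Consistent and Uncertain→Consistent; Worse is the three
enumerated downward moves; everything else — including *every* pair with an
Uncertain follow-up — is Other, because the downward moves are enumerated
exhaustively and an uncertain follow-up cannot witness a change. Baseline
is the questionnaire at the **first** test and follow-up the one at the
kth test (not the latest), matching the "kth test vs first test" design of
the reference comparisons; a missing condom response is read as Uncertain,
the role that category plays in the questionnaire.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the analysis assumes, with
ground truth retained for recovery tests:

- **Entry** uniform over the one-year window; the first test at entry.
- **Archetypes**: adherent (probability 0.10, the adherence level the
  reference cohort exhibits) drawing inter-test gaps uniformly on
  [30, 100] days; nonadherent drawing from a 0.35/0.65 mixture of
  uniform [30, 100] and uniform [101, 330]. No published inter-test
  distribution exists; these supports are the package's invention, chosen
  to bracket the 100-day threshold and the observed per-participant test
  counts, and they are deliberately *not* tuned further.
- **Stopping**: after each test, probability 0.30 of never testing again
  (default; chosen to put the mean test count near 2 per included
  participant, matching the reference cohort's 2634/1315).
- **Seroconversion**: exponential with archetype-specific hazards, 0.171
  and 0.048 per person-year — the rates observed in the two groups of the
  reference cohort. Hazards attach to the *archetype*, not the downstream
  label, avoiding circularity between generation and classification.
  Timelines truncate at the first positive test (a confirmed infection
  ends testing), which also guarantees clean validation reports.
- **Baseline positives**: probability 144/2702 of a single positive test
  at entry, exercising the cascade's exclusion branch.
- **Covariates** i.i.d. from the reference cohort's marginal composition,
  independent of archetype by default; an optional per-covariate log-odds
  tilt (`archetype_tilt`) creates a known covariate–archetype effect for
  logistic recovery tests (a tilt of δ on a binary covariate makes the
  true log odds ratio exactly δ).
- **Condom responses** follow a first-order Markov chain from the
  reference baseline mix (10, 162, 305, 203)/680 through a default
  transition matrix that drifts toward consistent use; the matrix is an
  invention (none is published) and is validated only for being
  row-stochastic and recoverable from simulated output.
- **Missingness** 5% in the three imputable covariates, under the
  reference's < 10% bound.

What the generator does *not* emulate: behavioral feedback of results on
testing frequency, covariate-dependent testing patterns (beyond the
optional tilt), seasonality, or loss to follow-up distinct from stopping.
Passing recovery tests therefore demonstrates that the estimators recover
the parameters of *this* data-generating process, not that real cohorts
satisfy its assumptions.

## Verification design and problem sizes

The suite pins every reproducible published statistic to its printed
precision and validates the machinery by independent dual routes:
brute-force gap enumeration against the classifier (10,000 random
timelines), closed-form 2×2 odds ratios against IRLS (1,000 tables),
hand-rolled logrank against the Cox score test, a distribution-level
Monte-Carlo oracle for the classified-adherent proportion of a simulated
5,000-participant cohort, Wald-interval coverage of the true log hazard
ratio over 500 two-group replicates of n = 2,000, and Garwood coverage
over 10,000 Poisson draws. Where the classified proportion is compared to
"truth", the truth is derived by an independent sampler from the
*configured gap distributions* (including seroconversion truncation and
the waiver), because under the nonadherent mixture a nonadherent-archetype
participant can legitimately classify adherent by chance — raw archetype
fractions are not the expectation of the classified proportion. The
rate-coverage Monte Carlo in the unit suite uses 120 replicates of
n = 1,200 cohorts with a 0.35 adherent fraction, sizes chosen to give
every interval enough events while keeping the default run desk-scale.

## Known limitations

- The "paper" CI dialect is a reproduction artifact, not a recommended
  interval; its containment in Garwood's means it is anti-conservative.
- The hot-deck imputation conditions only on the adherence label; with
  strong covariate–covariate dependence a chained-equations engine would
  be more faithful.
- Cox and logistic fits on very small cohorts (like the shipped
  6-participant fixture) are legitimately undefined and surface as logged
  notes, not estimates.
- The adjusted (multivariable) estimates of the reference analysis are not
  reproducible from aggregate data and are validated on synthetic cohorts
  only.
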