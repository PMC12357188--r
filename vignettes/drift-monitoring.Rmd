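---
title: "Monitoring performance drift in percentile-rank risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring performance drift in percentile-rank risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(candrift)
```

## The monitoring problem

Population health-risk algorithms such as the Veterans Health
Administration's Care Assessment Needs (CAN) score apply a *frozen*
logistic model to routinely collected covariates — demographics, diagnoses,
laboratory values and vital signs, pharmacy fills, and utilization — and
convert each patient's predicted 90-day hospitalization/mortality
probability into a percentile rank of 0–99 within the scored population.
Care programs then flag the top percentiles (typically CAN ≥ 90) as high
risk. The coefficients stay fixed after deployment while the population,
care-delivery patterns, and outcome rates move underneath them, so the
classification properties of the flag — not the model itself — degrade over
time. candrift measures that degradation, screens for the covariate and
outcome shifts behind it, tests whether retraining without the shifted
inputs helps, and quantifies the knock-on damage to a quality metric built
on the flag.

## The score and the percentile transform

For patient-year row $i$ with binary indicators $x_{i1},\dots,x_{ik}$ the
raw risk is

$$p_i = \operatorname{logit}^{-1}\!\Big(\beta_0 + \sum_j \beta_j x_{ij}\Big),$$

computed by `compute_raw_probability()` with the deployed
`coefficient_table()`; nothing is refit. `to_percentile()` then assigns,
within each scoring year,

$$\text{score}_i = \Big\lfloor 100 \cdot \frac{\#\{j : p_j < p_i\}}{n} \Big\rfloor \in \{0,\dots,99\}.$$

Two deliberate choices live here. Ranking is **per year**: pooling years
would let changes in yearly cohort size leak into every other year's
scores. And ties share the score of the *strictly-smaller* count (so a
fully tied year scores everyone 0); which tie rule the deployed system uses
is not documented, and the choice only moves tied boundary cases, but it is
pinned by tests so it cannot drift silently. `classify(scored, t)` flags
`score >= t` — the threshold is inclusive, matching the operational
"CAN ≥ 90".

Missing covariate values are not imputed at scoring time: the CAN design
encodes missingness as explicit indicator levels ("no result", "unknown"),
so panels must arrive fully dummy-encoded.

## Performance metrics and their edge cases

`compute_metrics()` produces TPR (sensitivity), FPR (1 − specificity),
PPV, NPV, F1 (harmonic mean of TPR and PPV), accuracy, and outcome
prevalence from the four confusion cells. Because every metric is a ratio
of cells, printed percentage tables work as well as raw counts — that is
how the package re-derives reported metric values from a published
classification-rate table (`metrics_from_published()`).

A metric with a zero denominator (e.g., PPV when nothing is flagged) is
returned as `NA`, never 0: a silent zero would fabricate drift when
differenced. `NA`s propagate through `drift()` to keep undefined changes
undefined. Supporting measures: `calibration_by_decile()` uses ten
*equal-count* bins of predicted probability (stable sort, so ties keep
input order; bin sizes differ by at most one), and `auc()` is the
Mann–Whitney rank statistic with half-credit ties, invariant under any
strictly monotone rescoring — in particular identical on raw probabilities
and percentile scores up to tie effects. Exact intervals for counts use the
Clopper–Pearson construction (`binomial_ci()`, via beta quantiles).

## Drift, affected patients, and the bootstrap

Drift is the **absolute change in percentage points, final minus
baseline**, over a period (`drift_periods()` defaults to the gradual
2016→2018, shock 2019→2020, and composite 2016→2020 spans, labelled in the
"score year (outcome year)" convention). A negative PPV drift is a PPV
drop. `affected_counts()` translates TPR/FPR changes into people:
|ΔTPR| × final-year cases and |ΔFPR| × final-year controls, rounded to
whole persons.

`bootstrap_ci()` resamples **patients**, not rows: a replicate draws
`n_individuals` patient ids with replacement and keeps *all* of a drawn
patient's yearly rows (k draws ⇒ every row k times), preserving
within-patient longitudinal correlation. Within each replicate the
percentile transform is recomputed — the ranking is part of the estimator —
while the coefficients stay fixed. Whether a deployed system would rerank
inside replicates is genuinely open; recomputation is the internally
consistent choice (the score *is* a rank), and freezing ranks instead can
be emulated by passing a pre-scored panel and a statistic that skips
`to_percentile()`. Intervals are the 2.5th/97.5th percentiles of the
replicate distribution. A statistic undefined in more than 10% of
replicates aborts with a diagnostic rather than quietly averaging the rest.

The default configuration is desk-scale: 10 000 individuals × 500
replicates. The operational analysis this emulates ran 1 000 000 × 2000;
when `n_individuals` is below the cohort size the intervals are
*conservatively wide* (they shrink like $1/\sqrt{m}$, which the test suite
checks by simulation), so desk-scale CIs err toward caution, never toward
false alarms.

## Covariate-shift screening and ablation

For binary indicators the standardized mean difference between years $a$
and $b$ is the pooled-Bernoulli form

$$\mathrm{SMD} = \frac{p_b - p_a}{\sqrt{(p_a(1-p_a) + p_b(1-p_b))/2}},$$

with the later year in the numerator (same sign convention as drift) and
SMD ≡ 0 when both prevalences are degenerate and equal. `screen_shifts()`
flags a covariate when |shift| is large (SMD ≥ 0.1 or < −0.1) and/or its
original predictive effect is large (OR ≥ 1.5 or < 0.5) — a pure,
idempotent threshold rule whose output doubles as the SMD-versus-OR
quadrant table behind a shift plot.

`retrain()` refits the logistic model on one training year by maximum
likelihood (relative deviance change < 1e−8, at most 100 iterations),
failing loudly on rank deficiency (naming the collinear columns) and on
apparent separation (any |coefficient| > 15). When dummy levels of one
categorical are grouped, excluding any level drops its siblings too —
dropping one dummy alone silently redefines the variable's reference level
(`expand_groups = FALSE` disables this). `ablation_compare()` then reruns
the *identical* score→rank→metric→drift pipeline under the original
coefficients, a baseline-year refit without the flagged covariates
(optionally per category), and later-year full refits, aligned for
side-by-side comparison.

## Quality-metric reliability

`quality_endpoints()` computes, per year × threshold: the quality metric
(share of flagged patients with a palliative-care visit), the
false-positive share among flagged patients (identically 1 − PPV on the
same rows — asserted by test), and the false-positive share among flagged
patients with a visit, each with exact intervals and explicit
numerator/denominator so every proportion is recomputable. The visit is a
per-year binary flag ("first palliative-care visit in the year"); the
procedure-code logic that defines a visit in a production system is
upstream of the panel, and fiscal-versus-calendar-year subtleties in
reported tables are not modelled — the panel's single `year` column is the
time axis.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws, per patient: a latent normal frailty (sd
`frailty_sd`) added to the logit and reused every year — the sole source of
within-patient outcome correlation, which the individual-level bootstrap is
designed to respect; then per year, independent Bernoulli covariate
indicators at that year's prevalence (mutually exclusive dummy groups are
drawn as one categorical), the outcome from the logistic model, and a
palliative visit with probability `plogis(a + b·logit(p))` increasing in
the true risk `p`. With `prevalence_targets` set, the intercept is
calibrated per year by deterministic root-finding on the mean predicted
probability over the realized draws (bracket ±30 on the logit, tolerance
1e−10), so realized prevalence matches the target in expectation without
rejection sampling; unreachable targets fail with a clear error. Identical
seeds give bit-identical panels.

`default_scenario()` encodes the qualitative drift story of the deployed
setting: five scoring years; 25 covariates across the five categories (the
three age dummies grouped); outcome prevalence declining monotonically
0.038 → 0.030, a smooth version of the reported pandemic-era drop from
~3.8% to ~3.0%; diagnostic and pharmacy indicators stable; and one
demographic (care-priority status), three laboratory/vital and four
utilization indicators shifted from the fourth year onward with analytic
|SMD| between 0.21 and 0.63 — utilization and laboratory measurement
patterns are exactly the inputs that moved during the pandemic. A shift
entry sets the covariate's prevalence from its year onward. Frailty sd 0.8
and the palliative link (−1.8, 1) were chosen once to give plausible
year-over-year outcome correlation and a ~2–3% quality metric among the
flagged decile.

What the generator deliberately does **not** emulate: real covariates are
correlated within a year (utilization drives lab availability) and shift
jointly, whereas the generator shifts marginals independently given the
year; there are no ICD/CPT code streams, no weekly score updates (one
score per patient-year), no hospitalization-at-scoring exclusions, no
entry/exit from the cohort, and the frailty is time-constant. Passing
tests therefore demonstrate that the *estimators and pipeline* behave as
specified under a known generating process — not that the synthetic
magnitudes transfer to any particular health system.

## Numerical and reporting conventions

Report tables round metrics to one decimal of a percent and
classification rates to two, matching how such tables are conventionally
printed; JSON outputs keep full precision. Affected counts are whole
persons. `run_all()` records the seed, a configuration fingerprint and the
package version in every output header, and two runs of one configuration
are byte-identical.

Problem sizes in the test suite are chosen so that Monte-Carlo noise is
small relative to each tolerance: bootstrap coverage is assessed over 500
simulated cohorts of 10 000 patients (500 replicates each), coefficient
recovery and monotone-trend checks run at 200 000 patients, and shift-flag
recovery at 100 000, where sampling error in an SMD is below 0.005.

```{r example}
cfg <- default_scenario(n_patients = 5000, seed = 7)
cohort <- generate_cohort(cfg)
scored <- score_panel(cohort$panel, cohort$coefficients)
round(metrics_by_year(scored, 90, exact_ci = FALSE)[,
  c("year", "prevalence", "tpr", "fpr", "ppv", "f1", "auc")], 3)
```

## Known limitations

Only binary (dummy-encoded) covariates are supported, matching the
deployed model's design but excluding continuous-input algorithms. The
SMD screen is univariate; joint shifts that cancel marginally are
invisible to it. Concept drift — a changing covariate–outcome relationship
at fixed distributions — is not modelled by the generator and not
separately identified by the screen. And the bootstrap quantile interval
is the percentile method; studentized or BCa variants are out of scope.
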