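---
title: "Methods: trial-based cost-effectiveness analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## The evaluation problem

`trialcea` implements a health-economic evaluation alongside a two-arm
randomized controlled trial, from the societal perspective, over a 6-month
horizon. The motivating setting is a guided internet-based stress-management
intervention (arm label `ISMI`) for employees with elevated perceived stress
(PSS-10 at or above 22 at inclusion), compared against a waitlist control
with unrestricted access to usual care (`WLC`). The package answers the
decision-maker's question: at a given willingness to pay per unit of health
gained, what is the probability that the intervention is cost-effective?

Because cost data are heavily right-skewed, significance testing of cost
differences is abandoned in favour of a probabilistic decision framework:
nonparametric bootstrapping of the joint distribution of incremental costs
and incremental effects, summarised on the cost-effectiveness plane and as
acceptability curves. No discounting is applied (the horizon is six months).

## Data model

Trial data are wide, one row per participant (`trial_schema()` documents all
44 columns): arm, PSS-10 at weeks 0/7/26, SF-6D and EQ-5D-3L utilities at
the same timepoints, gross monthly wage, and TiC-P-style resource-use counts
over two 3-month recall windows — the three months before baseline (`w1`)
and the three months before the 6-month follow-up (`w3`). Missing values are
empty cells, never sentinel zeros: a recorded cost of 0 is a real
observation. `dropout` is derived (follow-up PSS missing) rather than
stored. Costs are not assessed at week 7; the data model deliberately allows
only the two recall windows actually measured.

## Costing (2013 euros)

Each category cost is units of use times a standard unit price
(`read_unit_costs()`); the packaged service prices are synthetic
placeholders, while the rate constants are the standard figures for German
societal costing:

* car travel at 0.30 EUR/km, bus/taxi fares at face value;
* leisure time spent waiting for or receiving treatment at the opportunity
  rate 23.10 EUR/h (time spent using the intervention itself counts as
  leisure and is not valued — the default applies the rate only to reported
  waiting/treatment hours);
* informal care and domestic help by the substitution method at 18.33 EUR/h;
* prescription drugs as packages times the weighted package price: per drug,
  the mean price over the up-to-3 largest packages, computed separately
  under statutory and private insurance and combined with the statutory
  population share 0.888;
* absenteeism by the human capital approach: work-loss days times the gross
  daily wage (monthly wage divided by `workdays_per_month`, default 260/12 ≈
  21.67 — the divisor is a package choice, as the source guidance does not
  fix one);
* presenteeism via lost-workday equivalents: reduced-efficiency days times
  an inefficiency score in [0, 1], times the gross daily wage (a raw 0–10
  instrument score must be divided by 10 at ingest);
* the intervention as a flat 299 EUR tariff, intervention arm only.

Window costs are cumulated to six months by linear interpolation between the
two 3-month rates (area under the curve): the trapezoid
`(w1 + w3) / 2 * 6/3`, i.e. simply `w1 + w3`. The baseline window serves as
the month-0 rate anchor: baseline cost balance between arms is itself a
reported quantity, which argues for anchoring rather than doubling the
follow-up window. The alternative (`auc_method = "double_followup"`,
`2 * w3`) is available because the anchoring convention is a genuine design
choice. The intervention tariff is a one-off added to the 6-month total, not
interpolated — it is a flat price, not a rate. Amounts are indexed with the
consumer-price factor 1.04 (2010 to 2013) and converted to US dollars at the
2013 purchasing power parity of 1.29 where requested; internal computation
is at full precision, with half-up rounding to whole euros only at the
reporting stage (so rounded components need not sum to rounded totals).

## Outcomes

*Symptom-free status* is remission on the PSS-10: a follow-up score strictly
below the baseline sample mean minus two baseline SDs, 25.52 − 2·3.91 =
17.70 by default. The boundary is immaterial for integer scores. The strict
inequality is a package choice; the threshold itself is a parameter
(`outcome_config()`).

*QALYs* are the trapezoidal area under the utility curve across weeks
0 → 7 → 26, divided by exactly 52 weeks/year, so constant full health yields
0.5 QALYs over the horizon. No baseline utility adjustment is made (baseline
utilities are balanced by randomization in the emulated design); the SF-6D
is the primary instrument, the EQ-5D-3L a sensitivity instrument.

Descriptive statistics follow the conventional toolkit: mean pre–post PSS
change per arm, Pearson 2×2 chi-square (no continuity correction) for binary
contrasts, and the number needed to treat as the reciprocal risk difference.

## Missing data (intention to treat)

All analyses are ITT, so missing outcomes are imputed, never dropped.

*Clinical outcomes* (PSS and utilities at weeks 7/26) get proper multiple
imputation with `m = 10` completed datasets by default: for each incomplete
variable, a Bayesian normal linear regression on baseline predictors (arm,
baseline PSS, baseline utilities, wage) with posterior draws of the
coefficients and residual variance, then a draw from the predictive
distribution. This is a chained-equations normal-model approximation of an
MCMC multivariate-normal scheme; both amount to draws from a multivariate
normal posterior approximation. Imputed PSS scores are rounded and clamped
to 0–40, utilities to their instrument ranges. Observed values are never
altered, and the whole procedure is seed-deterministic.

*Costs* are imputed deterministically at the window-by-category aggregate
level (not per resource item, which would be ill-posed): a linear regression
of each follow-up-window category cost on arm, the same category's baseline
cost and the baseline predictors, with predictions floored at zero.
Predictors that are constant among observed rows are dropped; a genuinely
singular design falls back to arm-mean imputation with a warning.

The nesting order is: impute first, then bootstrap the completed data,
stacking bootstrap draws equally across the m outcome imputations and
averaging point estimates across imputations (Rubin's mean rule). Imputing
inside every bootstrap replicate is a defensible alternative; the simpler
stacking order is the package's documented choice.

## The decision analysis

Incremental costs and effects come from a seemingly unrelated regression of
the cost and effect equations, both on an intercept and the arm indicator,
with correlated residuals. With identical regressors SUR point estimates
coincide with equation-by-equation least squares — the arm-mean differences
— which the test suite asserts against a group-means oracle; the
cross-equation residual correlation is reported.

Uncertainty is handled by nonparametric bootstrap (default `B = 5000`):
participants are resampled with replacement *within arm*, preserving the
132/132 design, and the SUR estimates recomputed per draw. The cloud of
paired draws supports:

* the ICER `ΔC/ΔE`, with dominance semantics — negative ratios are
  meaningless, so more health at lower cost is reported as *dominant* and
  less health at higher cost as *dominated*; a zero effect difference leaves
  the ratio undefined rather than silently NaN;
* percentile 95% intervals (2.5th/97.5th percentiles, type-7 interpolation)
  for ΔC and ΔE; for the ICER, when the lower end of the cloud lies in the
  dominant quadrant the interval is reported as "dominant to X" with X the
  97.5th percentile of the ratio among north-east draws — an exact interval
  for a ratio spanning quadrants does not exist;
* the plane distribution: the percentage of draws per quadrant, east =
  positive effect, north = positive cost. Draws with exactly zero effect
  difference count as east, zero cost difference as south, so every draw is
  counted once and percentages sum to 100;
* the acceptability curve: at ceiling λ, the fraction of draws with positive
  net monetary benefit λ·ΔE − ΔC. CEAC(0) is therefore the probability of
  cost saving, and the curve is nondecreasing whenever all effect draws are
  nonnegative. Default grids: 0–5000 EUR (step 100) per symptom-free
  person, 0–50,000 (step 500) per QALY, 0–1000 (step 20) per PSS point.

Effect measures: PSS-point improvement, symptom-free status (analysed as a
linear-probability arm difference, which matches a GLM on the binary outcome
to the reported precision), and QALYs.

Scenarios (`run_scenario()`): `main`; `no_inpatient` (inpatient costs
removed — they are rare, ~3.4% of participants, but large enough to distort
means); `intervention_plus_100` / `intervention_minus_100` (tariff
uncertainty); `eq5d` (QALY instrument switch). Imputation and bootstrap
seeds derive from the top-level seed and the stage/effect label only — never
the scenario — so scenarios share resampling indices and a ±100 EUR tariff
offset shifts every draw's ΔC by exactly ±100.

## The synthetic trial generator

There is no deposited dataset, so `generate_trial()` produces trials with
the statistical structure the analysis assumes; its defaults are the
emulated study conditions:

* `n = 132` per arm; baseline PSS-10 from N(25.52, 3.91²) truncated below
  at 22, rounded to integers;
* PSS improvement to week 26 of 9.75 (ISMI) vs 3.0 (WLC) points, common
  SD 6; the week-7 score sits on the linear path with extra noise (SD 3, a
  package choice);
* SF-6D utilities: baseline mean 0.65 in both arms (SD 0.11 ISMI / 0.08
  WLC), rising by week 26 to a between-arm gap of 0.02 (0.015 at week 7),
  which implies a configured QALY difference of ≈0.0074 — the reported
  scale of the utility effect. EQ-5D utilities sit lower (baseline 0.55)
  with a smaller gap (configured QALY difference ≈0.0019), emulating the
  instrument's ceiling-effect insensitivity in mild conditions;
* utilities couple to concurrent stress through a Gaussian copula with
  correlation −0.4 (configurable): the exact dependence is not identified
  by published summaries, and −0.4 encodes a clinically real but moderate
  coupling. Stress is standardised within arm before coupling, so the
  copula shapes the joint distribution without moving the configured arm
  means;
* resource-use categories are zero-inflated lognormal (gamma selectable) in
  natural units, parameterised by `(p_zero, mean_units, sdlog)` with
  `mean_units` the unconditional mean — so `expected_summaries()` returns
  exact closed-form expectations. Category levels are calibrated loosely to
  the published per-arm 6-month cost means; exact matching of those tables
  is not claimed. Quantities are continuous (fractional units of use) to
  keep the moments exact;
* inpatient episodes are a separate rare/severe process: admission with
  probability 0.034, days lognormal with mean 14 (clamped at 92), assigned
  to one window at random;
* wages lognormal with median 3000 EUR/month (SD of log 0.35);
  inefficiency scores Beta(2, 5) — right-skewed on [0, 1], any such shape
  would do;
* dropout with probability 0.128 (ISMI) / 0.0833 (WLC), completely at
  random, deleting the week-7/26 outcomes and the entire follow-up window.

What the generator does *not* emulate: baseline cost balance between arms.
Category parameters are stationary across windows and arm-specific in both
windows, so arms differ (in expectation) already at baseline, unlike a real
randomized trial. Enforcing balance while hitting per-arm 6-month levels
would require negative follow-up means for low-use categories. Tests passing
on this generator therefore demonstrate the correctness of the analysis
machinery under a known joint distribution — not that the generator
reproduces any particular trial's data, nor that the analysis is robust to
informative dropout (dropout here is MCAR by construction).

## Numerical choices and degenerate inputs

Seed handling: every stochastic stage (generation, imputation, bootstrap)
takes a 32-bit seed derived deterministically from the top-level seed and a
stage label, so stages are independently reproducible and the end-to-end
report is byte-identical under a fixed seed. Degenerate configurations
(zero SDs, empty truncation mass, probabilities outside [0, 1]) are
rejected at construction. A zero risk difference makes the NNT undefined
(error, not Inf); a zero margin makes the chi-square undefined; costing a
missing window raises an error directing the user to impute first.
Residual correlations are reported as `NA` when either equation's residuals
are numerically degenerate.

## Problem sizes used by the test suite

Parameter-recovery properties (generator moments, MCAR imputation
unbiasedness, incremental-effect recovery) run at n = 2000 per arm with a
3-standard-error Monte-Carlo tolerance, dropout disabled where the property
concerns the generator/estimator chain rather than imputation. End-to-end
determinism and scenario algebra run at n = 40–60 per arm with B = 100–200
and m = 2–3; bootstrap consistency at B = 1000. These sizes are the
package's own test design: large enough for the stated tolerances, small
enough that the full suite runs in seconds.

## A worked run

```{r, eval = FALSE}
records <- generate_trial(generator_config(), seed = 2013)
report <- run_pipeline(records, B = 5000, m = 10, seed = 2013,
                       out_dir = "cea-report")
report$scenarios$main$effects$symptomfree$plane
plot_ceac(report$scenarios$main$effects$symptomfree$ceac)
```

## Known limitations

Costing consumes utilities and resource counts as numbers; instrument
scoring tariffs and drug-database lookups are out of scope (prices come from
a user-supplied or packaged table). The imputation models are normal-linear
on cost aggregates that are in truth zero-inflated and skewed — adequate for
mean recovery under MCAR, not a model of the full predictive distribution.
The bootstrap treats the m imputed datasets by equal stacking rather than
nesting imputation inside resampling, which mildly understates
between-imputation uncertainty when the missing fraction is large. The
generator's marginals are calibration targets, not estimates of any real
trial's joint distribution.
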