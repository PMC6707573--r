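# trialcea

Trial-based cost-effectiveness analysis from the societal perspective, for
health economists and trial statisticians evaluating an intervention
alongside a two-arm randomized controlled trial. The motivating application
is a guided internet-based stress-management intervention for employees with
elevated perceived stress (PSS-10 ≥ 22) against a waitlist control, over a
6-month horizon, but every threshold, price and grid is a parameter.

The package covers the full evaluation chain:

* **Costing** — TiC-P-style resource use priced with standard unit costs
  (2013 €): health-care services, prescription drugs (statutory/private
  weighted package prices), out-of-pocket and travel spend, opportunity
  costs of waiting time (23.10 €/h), informal care by the substitution
  method (18.33 €/h), absenteeism by the human capital approach, and
  presenteeism via lost-workday equivalents. Two 3-month recall windows are
  cumulated to 6 months by area-under-the-curve linear interpolation.
* **Outcomes** — symptom-free status (follow-up PSS below the baseline mean
  minus 2 SDs), QALYs as the trapezoidal area under the SF-6D (or EQ-5D-3L)
  utility curve, NNT, chi-square contrasts, mean PSS change.
* **Missing data** — multiple imputation of clinical outcomes (Bayesian
  normal regression, m = 10) and deterministic regression imputation of
  window-level cost aggregates, intention-to-treat throughout.
* **Decision analysis** — incremental costs and effects from a seemingly
  unrelated regression of cost and effect on arm,

  ```
  ICER = (C_ISMI − C_WLC) / (E_ISMI − E_WLC) = ΔC / ΔE
  ```

  bootstrapped B = 5000 times (stratified within arm), with dominance
  semantics, percentile 95% CIs, the cost-effectiveness plane quadrant
  distribution, and acceptability curves by net-monetary-benefit counting
  P(λ·ΔE − ΔC > 0). Sensitivity scenarios: exclude inpatient costs, shift
  the intervention tariff by ±100 €, switch the QALY instrument.
* **Synthetic trials** — `generate_trial()` draws datasets with the
  statistical structure the analysis assumes (truncated-normal baseline
  stress, arm-specific improvement, utility–stress copula, zero-inflated
  lognormal costs, rare severe inpatient episodes, MCAR dropout) with
  closed-form moments (`expected_summaries()`) for parameter-recovery
  testing.

## Worked example

```r
library(trialcea)

records <- generate_trial(generator_config(), seed = 2013)  # 2 x 132 participants
report  <- run_pipeline(records, scenarios = "main", B = 2000, m = 10, seed = 2013)
report
#> Trial-based cost-effectiveness report (B = 2000, m = 10, seed = 2013)
#> Scenario: main (B = 2000, m = 10, seed = 2013)
#>   pss          dCost =     -704 EUR  dEffect =   6.1076  ICER: Dominant (more effect, lower cost)
#>   symptomfree  dCost =     -704 EUR  dEffect =   0.3182  ICER: Dominant (more effect, lower cost)
#>   qaly         dCost =     -704 EUR  dEffect =   0.0067  ICER: Dominant (more effect, lower cost)
```

The intervention arm saves 704 € per participant over 6 months while gaining
6.1 PSS points, a 0.32 higher probability of being symptom-free, and 0.0067
QALYs — it *dominates* the control, so no ratio is reported. The bootstrap
cloud quantifies the uncertainty:

```r
e <- report$scenarios$main$effects$symptomfree
round(e$plane, 1)
#>   NE   SE   SW   NW
#>  9.6 90.4  0.0  0.0
e$ceac[e$ceac$wtp %in% c(0, 1000, 2000), ]
#>     wtp probability
#> 1     0      0.9045
#> 11 1000      0.9680
#> 21 2000      0.9900
e$icer_range
#> $lower: "dominant"     $upper: 3311.426
```

90% of bootstrapped incremental cost-effect pairs fall in the south-east
quadrant (more health, lower cost); even at a willingness to pay of 0 € per
symptom-free person the probability of cost-effectiveness is 0.90, rising to
0.99 at 2000 €. The 95% ICER summary runs from dominance to 3311 € per
symptom-free person. `render_table1(...)` (included in the report as
`$table1`) gives the per-arm mean costs by category, and `plot_ce_plane()` /
`plot_ceac()` draw the plane and the acceptability curve.

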