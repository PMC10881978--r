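# screencea

Accuracy is not cost-effectiveness. An AI grader for diabetic retinopathy
(DR) screening can be tuned to many operating points along its ROC curve,
and the most *accurate* one — the Youden-optimal sensitivity/specificity
pair — is not necessarily the one a health system should deploy: missed
referable disease progresses to irreversible, expensive blindness, while
false positives merely cost examinations. `screencea` is an R package for
quantifying that trade-off. It is aimed at health-economic modellers and
screening-programme analysts who want the full pipeline — operating-point
generation, cohort modelling, frontier analysis, uncertainty analysis — as
tested, composable functions rather than a spreadsheet or a point-and-click
model.

## What it computes

* **Synthetic screened cohorts** (`generate_cohort()`): participants with
  multiple fundus images, each image carrying a five-grade probability
  vector over the NHS grades (R0, R1, R2, R3s, R3a), class-conditional so
  the derived ROC has AUC ≈ 0.93, with configurable prevalence (default
  7.44%) and ungradable-image rate.
* **The two-step grade-level threshold sweep**
  (`sweep_operating_points()`): thresholds 0–0.9 in steps of 0.1 on the
  referable grades (10³ combinations), then on R0/R1 (10²), giving 1100
  participant-level operating points; `select_status_quo()` picks the
  Youden-optimal baseline and `empirical_auc()` the convex-hull AUC.
* **A decision-tree + Markov cohort model** (`run_cohort()`,
  `run_scenarios()`): annual screening of a closed cohort over 30 one-year
  cycles with referral compliance 50%, treatment compliance 70%,
  five clinical states plus screening-exit bookkeeping, state-and-age
  specific mortality, discounted costs (3%/yr) and QALYs (3.5%/yr).
  `microsim_oracle()` is an independent individual-level re-implementation
  used to validate the deterministic model.
* **Cost-effectiveness ranking** (`cea_frontier()`): ICER
  (= incremental cost / QALYs gained) and net monetary benefit
  (= incremental QALYs × WTP − incremental cost), strict and extended
  dominance, a WTP cut (default US$30,828/QALY = 3× per-capita GDP), labels
  against the status quo (*cost-saving* / *cost-effective*), and the best
  cost-effective scenario (BCES); plus `diagnostic_metrics()` (PPV/NPV) and
  `prevalence_wtp_grid()`.
* **Uncertainty** (`univariate_sweep()`, `run_psa()`): tornado-style ±10%
  (±20% for costs) perturbations, and Monte-Carlo probabilistic sensitivity
  analysis with beta/gamma parameter distributions and cost-effectiveness
  acceptability curves.

Everything takes and returns tibbles, chains with the pipe, and has
`tidy()`/`glance()`/`autoplot()` methods; `run_pipeline()` orchestrates the
whole chain and writes CSV/JSON outputs.

## Worked example

```r
library(screencea)

cohort <- generate_cohort(cohort_config(20000, seed = 1))
points <- sweep_operating_points(cohort$records, cohort$truth)
empirical_auc(points)
#> [1] 0.930

(sq <- select_status_quo(points))[, c("sensitivity", "specificity", "youden")]
#> # A tibble: 1 × 3
#>   sensitivity specificity youden
#> 1       0.917       0.779  0.696

params <- default_parameters()
scen <- run_scenarios(points, params)
fr <- cea_frontier(scen, wtp = params$wtp, status_quo = sq$scenario_id)
fr
#> <cea_frontier> 1100 scenarios, 6 on the frontier (WTP 30,828 US$/QALY)
#>   dominated: 1072  extended dominated: 10  above WTP: 12
#>   best cost-effective scenario: 155

tidy(fr)[match(select_bces(fr), tidy(fr)$scenario_id),
         c("scenario_id", "icer_vs_status_quo", "nmb", "label")]
#> # A tibble: 1 × 4
#>   scenario_id icer_vs_status_quo       nmb label
#> 1         155              3443. 94789392. cost_effective
```

Reading: of the 1100 operating points, 1072 are strictly dominated, 10
extended-dominated and 12 price QALYs above the willingness-to-pay
threshold; six scenarios survive. The best cost-effective scenario (id 155)
buys its extra QALYs at US$3,443 each — far below the US$30,828 threshold —
for a net monetary benefit of about US$95M over the cohort's 30 years, and
it has *higher sensitivity and lower specificity* than the most accurate
operating point. That inversion — accuracy-optimal ≠ cost-effectiveness-
optimal, with sensitivity the binding quality — is the phenomenon the
package is built to expose.

Absolute monetary results depend on cost/utility defaults that are
literature-range placeholders (see the methods vignette,
`vignettes/cost-effectiveness-methods.Rmd`); replace them with
setting-specific values via `load_config()` or the parameter constructors
before drawing real-world conclusions.

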