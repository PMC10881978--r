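---
title: "Methods: accuracy versus cost-effectiveness in AI-based DR screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accuracy versus cost-effectiveness in AI-based DR screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screencea)
```

## The question the package answers

An automated grader for diabetic retinopathy (DR) emits, for every fundus
image, a probability vector over the five NHS grades R0 (no DR), R1
(background DR), R2 (pre-proliferative), R3s (static proliferative) and R3a
(active proliferative). Referable DR means grade R2 or worse. The grader's
operating point — its sensitivity/specificity pair at the participant level —
is not fixed: grade-level decision thresholds move it along a receiver
operating curve. The most *accurate* operating point (the Youden-optimal
ROC cut-off) is not automatically the most *cost-effective* one for a
long-running screening programme, because sensitivity and specificity have
asymmetric economic consequences: missed referable disease progresses to
blindness, which is expensive and irreversible, while false positives only
waste examination capacity. `screencea` makes that trade-off computable: it
couples a grade-level threshold sweep to a health-economic cohort model and
ranks every operating point by incremental cost-effectiveness ratio (ICER)
and net monetary benefit (NMB).

## The threshold sweep

Thresholds come from the grid 0, 0.1, ..., 0.9, imposed per grade in two
steps: step 1 varies the three referable-grade thresholds with R0/R1 pinned
at zero ($10^3$ combinations, aimed at reducing false positives); step 2
varies the R0/R1 thresholds with the referable grades pinned at zero
($10^2$ combinations, aimed at reducing false negatives). That yields 1100
operating points. A grade is *activated* when its probability strictly
exceeds its threshold — strictness makes a zero threshold mean "always in
play", which the construction requires — and an image's final grade is the
activated grade of highest probability. A participant screens positive when
any gradable image is graded R2+ **or** any image is ungradable; routing
ungradable participants to referral mirrors real screening practice and is
the reason participant-level specificity is markedly lower than
image-level grader specificity. Duplicate (sensitivity, specificity) pairs
arising from different threshold vectors are deliberately retained: the
unit of analysis is the scenario, not the unique ROC point.

The *status quo* is the maximum-Youden point (ties: higher sensitivity,
then enumeration order). "Most accurate" is not well defined for a single
operating point; Youden's J is the standard ROC-cut-off criterion and is
what `select_status_quo()` implements — users can pass any other row of
the sweep as their baseline. The sweep AUC is the trapezoidal area under
the upper-left convex hull of the point cloud augmented with (0,0) and
(1,1); note the hull estimator is biased upward on small noisy clouds,
which is why calibration checks use cohorts of 20,000 participants.

## The synthetic cohort generator

The real screening data behind this kind of analysis is private, so the
package ships a generator that reproduces the *statistical structure* the
analysis needs, not the images. Each participant carries one latent true
grade: negatives split R0:R1 = 5:1 (the programme-level ratio also used to
pool non-referable utilities), positives split 60/15/25% across
R2/R3s/R3a (predominantly pre-proliferative disease, as screening
populations show). All of a participant's images (default 4: one
macula-centred and one disc-centred per eye) share that latent grade —
this within-participant correlation matters because the "any positive
image" rule would otherwise inflate participant-level sensitivity.
Gradable images draw their probability vector from a Dirichlet
distribution with concentration 8 whose mean interpolates between the
uniform simplex point (`class_separation = 0`, chance grading) and the
true grade's vertex (`class_separation` large, perfect grading). The
default `class_separation = 1.97` was calibrated once, by bisection
against `empirical_auc(sweep_operating_points(...))` at n = 20,000, to
land the sweep AUC at ≈ 0.93, the accuracy class of validated DR graders;
it is not meant to be re-tuned per analysis. Default prevalence is 7.44%.
Ungradable images are flagged independently per image; the rate defaults
to 0 because published programmes rarely report it — it is a free
parameter.

What the generator does *not* emulate: image content, camera or field
geometry, grader-specific error correlations across grades, and
participant covariates beyond the referable flag. Tests passing on
synthetic cohorts therefore validate the *machinery* (sweep, model,
frontier), not any claim about a particular real dataset.

## The cohort model

A hybrid decision tree + Markov cohort model follows a closed cohort
(default 251,535 participants, mean entry age 60) through 30 one-year
cycles. The five clinical states — non-referable DR, referable DR, treated
referable DR, blindness, death — are expanded with screening-eligibility
bookkeeping, because the screening workflow names exit rules a five-state
chain cannot express: treatment acceptors continue treatment and skip
future screening; treatment refusers and the blind also leave the
screening pool; false negatives *do* re-enter screening the next year
(they were never referred, so nothing removes them — this is an
assumption, flagged here, since the workflow does not state it
explicitly).

Within each cycle events happen in a fixed order: **screen** (everyone
still in the pool pays the per-person screening cost) → **refer**
(positives attend confirmatory examination with probability 0.50) →
**treat** (confirmed referable DR accepts treatment with probability
0.70; year-1 treatment cost on entry, follow-up cost in later years) →
**progress** (non-referable → referable at 0.07/yr; untreated referable →
blind; treated referable → blind; one transition per cycle) → **die**
(age-specific mortality times a state hazard ratio, clamped at 1) →
**accrue** (costs and utilities at end of cycle, discounted by
$(1+d)^{-\text{cycle}}$ with $d$ = 3% for costs and 3.5% for QALYs). The
ordering is a modelling choice — screening logically precedes that year's
progression — and is documented so alternatives can be tested; there is no
half-cycle correction, end-of-cycle accrual being the simplest auditable
convention. Blindness costs decompose as 53.2% direct medical + 6.4%
direct non-medical + 40.4% indirect; only the indirect share recurs after
the first year.

Rates convert to probabilities by $p(t) = 1 - e^{-rt}$
(`rate_to_probability()`). The non-referable utility pools the R0 and R1
utilities 5:1 (`weighted_nonreferable_utility()`); the per-person
screening cost is assembled from itemized programme components — cameras,
personnel throughput of 288 participants/day per six-camera team, AI
engineering at US\$0.214/participant, advertisement — with a calibrated
participant-side residual (transport, food, income loss) making the total
US\$10.65 (`build_cost_set()`).

Several parameters are published only in ranges, not point values:
referable→blind and treated→blind progression (defaults 0.054 and 0.012,
encoding the reported 4.5-fold annual blindness-risk ratio of untreated
over treated disease), examination/treatment/blindness costs (the
US\$4,000 year-1 blindness cost is the upper LMIC estimate), state
utilities (0.74/0.81/0.52), mortality hazard ratios, and the mortality
table itself (a synthetic Gompertz curve: hazard 0.008/yr at 60, 8-year
doubling — the broad shape of adult all-cause mortality; real census life
tables slot in via `natural_history(mortality_table = ...)`). All are
config-replaceable placeholders, and the package makes no claim to
reproduce any published absolute per-person cost or QALY figure — those
depend on the full unpublished parameter tables. Correctness of the model
itself rests on properties instead: cohort-mass conservation every cycle
(tolerance $10^{-6} n$, enforced at run time), closed-form QALY totals in
degenerate limits ($u \sum_k (1+d)^{-k}$), monotonicity of QALYs in
sensitivity and of false-positive examination cost in specificity, and —
most stringently — agreement with `microsim_oracle()`, an independent
individual-level stochastic re-implementation of the identical event
rules, within 3 Monte-Carlo standard errors at 20,000 individuals across
a lattice of parameter corners.

## Ranking scenarios

With population totals $(C_i, E_i)$ per scenario, `cea_frontier()` applies
the standard selection workflow: remove strictly dominated scenarios;
remove extended-dominated ones (iterating until the incremental ICER
sequence along the frontier strictly increases); truncate where the
frontier ICER exceeds the willingness-to-pay threshold (WTP, default
US\$30,828/QALY = 3× per-capita GDP; presets for 1× GDP and rural/urban
settings ship with the package). Survivors are labelled against the
status quo: cheaper ones *cost-saving*, the rest *cost-effective*. The
best cost-effective scenario (BCES) is the survivor of maximum effect,
ties to the lower cost. Undefined ICERs (zero incremental effect) are
never divided through — dominance logic handles them — and the
sign-ambiguous ICERs of cheaper-but-less-effective scenarios are reported
but never used for ranking; NMB and the cost-saving label carry that
information instead. Exact cost/effect duplicates share the fate of one
representative, so the 1100-scenario frontier is well defined despite
repeated operating points. A standard theorem says the ICER-stepped
frontier choice at WTP $\lambda$ equals $\arg\max_i (E_i \lambda - C_i)$;
the test suite verifies both this and the full label set against a
definition-based brute-force oracle on random scenario clouds.

`prevalence_wtp_grid()` repeats model + frontier across prevalence levels
(4/8/12% by default) and a WTP grid; on synthetic cohorts it reproduces
the qualitative pattern that higher prevalence and higher WTP demand
higher sensitivity from the grader.

## Uncertainty

`univariate_sweep()` perturbs one parameter at a time (±10%; ±20% for
costs; probabilities clamped to [0, 1]) and flags whether the BCES
identity survives at both bounds. `run_psa()` samples all parameters per
draw — beta distributions for probabilities, utilities, prevalence and
transition probabilities (compliance included, as an implied member of
that family), gamma for costs, both fitted by method of moments — and
records the NMB-optimal scenario per draw and WTP level, with ties broken
uniformly at random to keep the acceptability curve unbiased. Published
analyses of this design do not report their parameter dispersions, so the
defaults (SE = 10% of the mean for beta, 20% for gamma) mirror the
univariate ranges and are overridable in the distribution table;
consequently no specific published acceptability percentage is a
reproduction target. Invalid draws are resampled with a warning above a
1% rate. The formal default is 10,000 draws; checks in this package use
500 draws on a 2,000-person cohort, where the CEAC already concentrates
on the deterministic optimum as dispersions shrink and the PSA means stay
within 3 Monte-Carlo SEs of the deterministic run.

## Problem sizes and numerical choices

The test suite and the acceptance script use cohorts of 300–20,000
participants (20,000 for AUC calibration and micro-simulation
equivalence, where Monte-Carlo error is the binding constraint; smaller
for property tests), 30-cycle horizons throughout, 100 random scenario
clouds for the frontier oracle, and 500-draw PSAs. Determinism: every
random stage takes an explicit integer seed; equal seeds give
byte-identical tables. Floating-point care: the threshold grid is built
as `(0:9)/10` so grid values compare exactly; frontier tie-breaks are
specified (not left to sort stability); the convex hull uses
cross-multiplied slope comparisons to avoid division.

## Limitations

Diabetic macular oedema and visual-acuity states are out of scope (the
underlying screening data does not carry them); there is no treatment
waning, no individual heterogeneity beyond the micro-simulation oracle,
no per-eye analysis, no continuous-threshold ROC, and no budget-impact
analysis. The "no screening" comparator is expressible (sensitivity 0 with
zero screening cost) but not parameterized as a reproduction target. All
absolute monetary results depend on placeholder cost/utility defaults and
should be re-derived with setting-specific configuration before any
real-world use.

```{r example, eval = FALSE}
# end-to-end sketch
cohort <- generate_cohort(cohort_config(20000, seed = 1))
points <- sweep_operating_points(cohort$records, cohort$truth)
params <- default_parameters()
scen <- run_scenarios(points, params)
fr <- cea_frontier(scen, wtp = params$wtp,
                   status_quo = select_status_quo(points)$scenario_id)
glance(fr)
autoplot(fr, per_person = params$cohort$n)
```
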