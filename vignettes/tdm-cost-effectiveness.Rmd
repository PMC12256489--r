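---
title: "Modelling the cost-effectiveness of perampanel drug monitoring in pediatric epilepsy"
author: "tdmcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of perampanel drug monitoring in pediatric epilepsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmcea)
```

## The question and the model

Perampanel plasma concentrations correlate with seizure control in children,
so measuring the concentration and steering the dose into the 100–1000 ng/mL
therapeutic range (therapeutic drug monitoring, TDM) should improve
outcomes — at the price of testing and closer follow-up. The package asks
whether that trade is worth making from a healthcare-system perspective.

The decision model is a two-arm, four-state Markov cohort model. States are
defined by seizure-frequency reduction versus baseline over a 6-month cycle:

* **no response** — less than 50% reduction;
* **response** — at least 50% but not 100%;
* **seizure freedom** — 100% reduction (a follow-up frequency of zero);
* **discontinuation** — the child stops perampanel and switches to other
  anti-seizure medications.

Every child enters in *no response*. Seizure freedom and discontinuation are
absorbing: the observed transition rows place no mass out of either state,
and discontinued children keep accruing medication, outpatient and
hospitalization costs until the horizon. Each state carries a per-cycle cost
(USD 2022; RMB inputs converted at 6.73 RMB/USD and inflated at 1.48%/yr)
and an SF-6D utility (0.500 no response / discontinuation, 0.597 response,
0.650 seizure freedom). Four mild adverse events (dizziness, somnolence,
irritability, ataxia) occur with arm-specific per-cycle probabilities while
on perampanel, each costing $318.70 and subtracting 0.0047 QALY per expected
event; the monitored arm's event rates are lower. The decision statistic is
the incremental cost-effectiveness ratio ICER = ΔC/ΔE of monitoring versus
no monitoring, judged against $12,814/QALY ("highly cost-effective") and
$38,442/QALY.

## From one printed transition table to two arms

The source tables print a single set of transition rows plus an odds ratio
(OR 0.461, 95% CI 0.220–0.965) contrasting the unmonitored with the
monitored arm, without stating which arm the rows describe or how the OR
enters. We resolve this with an explicit calibration rather than a guess.

`apply_or_adjustment()` shifts a transition row on the cumulative-logit
scale: for each cut j of the ordered destinations,
odds′(dest > j) = OR × odds(dest > j). Two cut sets are implemented:

* `on_per`: discontinuation is held fixed and the shift acts on the
  conditional ordering no response < response < seizure freedom;
* `four_state`: discontinuation is the worst ordered outcome
  (discontinue < no response < response < seizure freedom) and all three
  cuts shift, so a smaller OR also means more discontinuation.

`build_arm_matrices()` combines a cut set with an attribution mode — the
printed rows are the monitored arm, the unmonitored arm, or the pooled
cohort (in which case the two arms are shifted symmetrically by ±½ log OR) —
and a scope (first cycle only, or both phases). The pooled reading has
direct support in the data: the printed first-cycle discontinuation
probability, 29.2%, equals 35/120, the dropout fraction of the *entire*
cohort, and the source states that the second-cycle-onward rows are shared.

## Calibration of the unstated conventions

`calibrate_config()` runs all 48 combinations of attribution mode (3), cut
set (2), scope (2), effect-discount rate (5% or 0) and reward convention
(below) over the base case and the 1-, 5- and 10-year horizons, scoring each
candidate by its worst relative error against the published per-arm costs,
QALYs and ICERs. All candidates are reported; the winner ships as the
`model_config()` default.

Two reward conventions are swept because the published totals cannot be
reproduced under the textbook one (first reward undiscounted, cycle *t*
discounted by (1+r)^(−(t−1)·0.5), QALY = utility × cycle length). Working
backwards from the published horizon rows: the difference between the 15-
and 10-year cumulative costs is only consistent with a 5% discount applied
**once per 6-month cycle**, the 1-year totals require a reward for the entry
state (cycle 0), and QALYs of ~1.5 over two 6-month cycles require utilities
accrued **per cycle without the half-year scaling**. The calibrated
convention therefore treats each cycle as one discounting period and counts
the entry state; the textbook convention remains available via
`discount_basis = "annual"`, `include_entry_cycle = FALSE`,
`qaly_scale = "per_year"`, and `discount_factor()` implements the textbook
formula directly. A consequence worth keeping in mind: the calibrated QALY
totals are roughly twice the "true" discounted quality-adjusted *years*; the
ICER inherits the same convention, which is what makes it comparable to the
published numbers.

The selected configuration is: pooled attribution with the symmetric ±½ log
OR shift, `four_state` cuts, first-cycle scope, 5% per-cycle discounting of
both costs and effects, entry-cycle reward, per-cycle utility accrual, the
printed discontinue-state cost total (787.31, both arms) and adverse events
restricted to the on-treatment states. Under it the base case and all three
horizon ICERs fall within 10% of the published values (the 1-year horizon is
the binding one at about −9%); the acceptance script recomputes all four.

Other conventions in the selected configuration: the discontinue-state cost
is the printed 787.31 in both arms — notably, 787.31 is exactly the mean of
the two arms' component sums (681.21 / 893.40), which are available via
`dc_cost_mode = "components"`; the adverse-event disutility is applied per
expected event and cycle without cycle-length scaling, matching its cited
per-event magnitude; half-cycle correction is off by default (not part of
the source model) but implemented.

## Source-table inconsistencies the package handles explicitly

* **Outcome counts.** The printed 12-month unmonitored-arm cells
  (8, 10, 4) sum to 22, but the completer count is stated as 24 and every
  published rate (16.7% = 4/24, 58.3% = 14/24) requires 24. The packaged
  table stores the reconstructed cell (uncontrolled = 10); with the printed
  8 the headline rates are arithmetically impossible.
* **The odds ratio.** The published OR 0.461 (0.220–0.965) is *not* the
  maximum-likelihood cumulative-logit estimate for any arrangement of the
  tabulated counts we tried (2×3 completers: 0.250 reconstructed / 0.293
  printed; four levels with discontinuation lowest: 0.41;
  adjacent-categories: 0.42). It was presumably estimated on patient-level
  data with covariate adjustment. `fit_proportional_odds()` reports the
  honest MLE for the table it is given — verified against both an
  independent grid-search oracle and `MASS::polr` — while the Markov model
  takes the published 0.461 as an input parameter, so the economic results
  are unaffected.
* **Hospitalization components.** The identity probability × number × days ×
  daily cost = printed total holds within 1% for three of six printed cells
  (the monitored-arm response cell is off by 76%). The loader reports these
  as validation warnings instead of refusing the tables, and the one-way
  analysis perturbs components through cost *deltas* added to the printed
  totals, so the inconsistency cannot leak into the base case.
* **Drug names.** "XXP" in the combination table is stored as NZP
  (nitrazepam) and "XBN" in the price list as VGB (vigabatrin); each appears
  exactly where the respective drug is otherwise missing.

## The 240-parameter registry, tornado and probabilistic analysis

`build_param_registry()` enumerates every uncertain input: per arm the 4
adverse-event probabilities and costs, 4 state cost totals, 12
hospitalization components, the discontinue-state hospitalization total, 4
outpatient counts, 4 consultation costs, 4 outpatient totals, 3 perampanel
costs, 4 other-ASM costs, 52 drug-combination probabilities (the
discontinue-state profile mirrors the no-response one, as the other printed
discontinue rows do) and the 4 derived first-cycle transition
probabilities — plus the monitoring count and unit cost in the monitored
arm, the 12 pooled transition probabilities, and the shared odds ratio, 4
utilities, 4 event disutilities, test and examination costs, 14 drug unit
prices and the discount rate: 240 in all. Printed intervals are used
verbatim as one-way ranges; otherwise the range is mean ± 1.96 × (20% of
mean), the source's stated standard-error rule.

One-way analysis perturbs one entry at a time: transition cells are reset
and the rest of the row rescaled proportionally (rows stay stochastic while
isolating the named factor); component perturbations enter as deltas on the
printed state totals; the odds ratio re-derives the arm rows. Distribution
families follow the source's assignment — gamma for costs (and, on its
magnitude, the event disutility and monitoring count), beta for
probabilities, normal for utilities and outpatient counts (the source's
methods text assigns normal to utilities; its table says beta — we follow
the text, truncating to [0, 1] by resampling), lognormal for the odds
ratio — parameterized by method of moments from the base value and standard
error (log-scale for the lognormal, so exp(mean log) equals the base).

The probabilistic analysis samples every registry entry independently per
draw with one deliberate exception: the 8 derived first-cycle cells are
recomputed from the *sampled* pooled row and *sampled* odds ratio, keeping
the two arms coupled through the OR — the method's central uncertain
quantity — instead of letting independently sampled rows wash it out.
Sampled transition rows are renormalized to sum to one. The acceptability
curve is the fraction of draws with positive net monetary benefit
λ·ΔE − ΔC; it is exactly non-decreasing in λ over the draws with ΔE > 0,
and the full curve's endpoints count cost-saving draws (λ = 0) and
effect-gaining draws (λ → ∞). The published probability of being highly
cost-effective is reproducible only up to sampling and parameterization
uncertainty (the source states neither its random stream nor exactly which
entries it sampled); our runs land a few points above it, within the band
the acceptance criteria allow.

## Scenarios

`run_scenario()` implements: time horizons (only the horizon changes);
monitoring for the first year only (the monitored arm keeps its matrices,
costs and event profile for cycles 1–2, then switches to the unmonitored
arm's — dropping the monitoring testing cost with them — while retaining its
accumulated state occupancy); and user-supplied parameter overrides, the
vehicle for the newly-diagnosed and refractory subgroups whose inputs are
not published and therefore cannot be reproduced here.

## The synthetic cohort generator

`generate_cohort()` emulates the patient-record structure the estimators
consume: per-arm sample sizes default to the study's 78/42; each child draws
a log-normal baseline frequency (median 6 seizures/28 days, log-sd 0.8 — a
typical spread for children starting adjunctive perampanel), then moves
through the true first-cycle and subsequent-cycle rows (defaults: the
calibrated arm matrices); follow-up frequencies are constructed *exactly*
consistent with the drawn category (0 for seizure freedom, a uniform
reduction in [50%, 100%) for response, [0%, 50%) for no response), so
classification round-trips with probability one; discontinuation is a
competing destination in the same multinomial draw; period costs are gamma
draws around the per-category state means with a 20% coefficient of
variation, and the monitoring count is gamma with mean 1.74 per cycle. The
generator is fully reproducible from its mandatory seed.

What it does *not* emulate — and what passing tests therefore do not show
about real data: no within-patient cost correlation, no covariates
(age, epilepsy type, co-medication) and hence no confounding, no
concentration–dose pharmacokinetics, no seasonal or visit-window effects,
and frequencies are continuous rates rather than integer counts. It
validates the estimators and the pipeline plumbing, not the clinical
realism of the inputs.

Test problem sizes were chosen to make the statistical checks sharp but
quick: transition-row recovery uses 100 replicates of 2,000 children per arm
judged by 95% chi-square acceptance regions; odds-ratio interval coverage
uses 100 replicates of 500 per arm under a single-transition design whose
completer distributions satisfy the proportional-odds contrast exactly;
consistency is checked at 10,000 per arm.

## Numerical choices

Row stochasticity is enforced at 1e-9; traces conserve mass to the same
tolerance. The ordered-category boundary "a reduction of exactly 50% counts
as response" is computed as `2·followup ≤ baseline`, exact in floating
point. The proportional-odds likelihood is maximised by BFGS with an
analytic score and then Newton-polished to a gradient below 1e-11, so the
fit is symmetric under arm-label swaps to ~1e-15 and matches a grid-search
oracle to 1e-6 in log-likelihood; Wald intervals use the observed
information. Complete separation (an arm entirely in one extreme category)
is detected up front and signalled. Beta method-of-moments fits clip the
variance to 95% of its feasible maximum; degenerate spreads collapse to
point masses. A structurally zero transition probability stays zero under
any odds-ratio shift.

## Known limitations

The model inherits the source's structure: no mortality or background-death
state, no patient-level microsimulation, no correlation between sampled
parameters, and an adverse-event layer tied to treatment exposure only. The
calibrated reward convention reproduces the published accounting rather
than textbook discounting — comparisons with other analyses should use the
`annual` basis and per-year QALY scaling instead. The published odds ratio
and the printed outcome table cannot both be right; we document the
discrepancy rather than resolve it. Subgroup scenarios require
user-supplied inputs.
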