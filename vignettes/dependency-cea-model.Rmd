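---
title: "A five-state Markov cohort model for the cost-utility of health promotion in older people"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A five-state Markov cohort model for the cost-utility of health promotion in older people}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The model

`markovcea` implements a deterministic Markov cohort model for evaluating
the long-term cost-effectiveness of brief health-promoting interventions —
group-based senior meetings and a one-off preventive home visit — offered
to community-dwelling older people at risk of functional decline, against a
no-intervention comparator.

The health-state space has five levels defined by dependency in basic and
instrumental activities of daily living (ADL/IADL) and place of residency:

* **mild** — independent in basic ADLs, dependent in at most one IADL;
* **moderate** — regularly dependent in more than one IADL;
* **severe** — dependent in at least one basic ADL, help daily;
* **total** — extensive help throughout the day, ordinary or special
  housing;
* **dead** — absorbing.

A cohort (everyone starting in mild dependency, the trial inclusion
criterion) is propagated through an annual row-stochastic transition matrix
for a 4-year horizon: `share'[to] = sum_from share[from] * p[from, to]`.
Recovery, stability and decline are all allowed except total → mild, which
is structurally zero, and death is strictly absorbing; `validate_matrix()`
enforces these invariants along with row sums (tolerance 1e-9) on every
matrix that enters the engine.

Each state carries a health-related quality-of-life utility (0–1) and an
annual societal cost (EUR: health care, home help, informal care, special
accommodation). Accumulated outcomes over horizon $H$ are

$$\mathrm{QALY} = \sum_{t=1}^{H} (1+r)^{-t} \sum_s \pi_t(s)\,u(s), \qquad
\mathrm{Cost} = \sum_{t=1}^{H} (1+r)^{-t} \sum_s \pi_t(s)\,c(s) +
\sum_{t=1}^{H} (1+r)^{-(t-1)} e_t,$$

with $r = 0.03$ per year and $e_t$ the per-person intervention spending
committed at the start of cycle $t$.

### Outcome timing and discounting

Occupancy is measured at the end of each cycle and cycle-$t$ state outcomes
are discounted by $(1+r)^{-t}$; no half-cycle correction is applied. This
choice reproduces the published accumulated control-arm outcomes (2.355
QALYs, 24,291 EUR) to within 0.5% and the published per-year count table
cell-for-cell; adding a half-cycle correction worsens agreement, so the
model the shipped parameters were evidently built with is end-of-cycle.
Intervention spending is timed at the start of the year it buys:
the upfront cost (cycle 1) is undiscounted, and a booster delivered at the
start of year $t$ is discounted by $(1+r)^{-(t-1)}$ — one year less than
that year's state costs.

## Parameters

The shipped parameter set (`dependency_model_params()`, stored as plain CSV
and YAML under `inst/extdata/` and guarded by a fixture-drift test) holds:

* the annual transition matrix (mild row 0.79/0.13/0.03/0.02/0.03, etc.);
* utilities 0.77/0.60/0.47/0.41/0 and annual costs
  2,600/7,801/20,708/62,407/0 EUR;
* one-year trial arm counts: control 87/19/6/0/2 of 114, senior meetings
  (SM) 149/11/3/3/5 of 171, preventive home visit (PV) 150/19/1/0/4 of 174;
* itemised intervention cost sheets totalling 27,293 EUR (SM, 171
  participants → 160 EUR/head) and 12,337 EUR (PV, 174 → 71 EUR/head),
  with booster unit costs of 19 EUR (one extra senior meeting) and 71 EUR
  (one extra home visit);
* discount rate 0.03/year, horizon 4 years, reporting cohort 100 persons.

The itemised amounts are taken as printed rather than re-derived from the
underlying salary/time micro-accounting, which is not fully reconstructible
from the available figures (e.g. the rented-rooms item differs slightly
from sessions × room rate). The scenario engine consumes the *rounded*
per-participant costs (160/71/19/71 EUR), the form in which the costs are
reported and reasoned with; unrounded values remain available via
`per_participant_cost(sheet, "none")`.

## Intervention effects

Effects act once, in the first model year, as a reduced risk of leaving
mild dependency; from year 2 everyone reverts to the baseline matrix. They
are derived from the one-year trial counts as relative risks (RR) and
applied to the mild row only. Because the source tables pull in different
directions — the narrative arithmetic quotes per-destination RRs (0.35 SM,
0.65 PV for mild → moderate) while the published count table is only
consistent with a pooled effect — four application conventions are
first-class and selectable:

* `overall_rr_nondeath` (**default**): one pooled progression RR (all
  non-mild destinations, deaths included in the counts) scales
  mild → moderate/severe/total; mild → dead stays at baseline; all saved
  mass accrues to staying mild. This is the only convention we found that
  reproduces the published year-1 cells (SM mild 87, SM moderate 7, PV
  moderate 8): per-destination RRs give SM moderate 5, and raw treated
  proportions give PV moderate 11.
* `per_destination_rr`: each destination scaled by its own RR.
* `direct_proportions`: the mild row replaced by the treated arm's observed
  proportions.
* `moderate_only_rr`: only mild → moderate scaled (the narrative RR).

A control-arm destination with zero events (total dependency) yields an
undefined RR (0/0); such destinations are left unmodified — no information
is not evidence of protection. RRs are computed on unrounded fractions; an
`as_printed` mode reproduces the two-decimal worked arithmetic
(0.06/0.17 = 0.35) for documentation parity only.

The sensitivity attenuation `effect_scale` moves every effective RR
linearly toward 1: $RR_{\mathrm{eff}} = 1 - s\,(1 - RR)$, so $s = 0.8$ is
the "20% reduced effect" variant and $s = 0$ recovers the baseline matrix
exactly.

## Scenarios, boosters and sensitivity analyses

`run_scenario()` composes per-cycle matrices: the effect-modified matrix in
year 1 only (main analysis) or in every year (`booster_all_years`). Yearly
boosters are delivered to those who remained in mild dependency; since the
effect touches only the mild row, applying the modified matrix to the whole
cohort is mathematically identical to treating mild-state occupants alone
(asserted by a unit test). The booster cost for year $t \in \{2..H\}$ is
the booster unit cost times the mild-state share at the end of year $t-1$.

`sensitivity_suite()` runs two independent one-way variants: intervention
(upfront and booster) costs × 1.2 with effects unchanged, and
`effect_scale = 0.8` with costs unchanged. `incremental_analysis()`
classifies the cost-effectiveness quadrant; ICERs are reported only for
genuine trade-off quadrants, because a ratio of a QALY gain and a cost
saving (or the reverse) has a sign that invites misreading — dominant and
dominated pairs get the label instead. The comparator is always the
no-intervention scenario; senior meetings vs home visit is available as a
derived convenience, not a primary output.

```{r}
ref <- reference_analysis()
subset(ref$cea_table, analysis %in% c("main", "booster"))
```

## Reporting conventions

Person-count tables (`occupancy_report()`) scale unrounded shares to the
cohort and round half-up per cell; base R's banker's rounding is never used
for display. Rounded values are display-only and never re-enter
propagation. Monetary outputs are written in whole euros and QALYs to three
decimals, mirroring the precision of the source tables; full precision is
retained internally.

Two cells of the published count table sit essentially on rounding
boundaries and come out one person higher here: PV mild in year 1 computes
to 86.52 (→ 87, printed 86) and SM mild in year 2 to 69.50 (→ 70, printed
69). Whether the original spreadsheet floored those cells or worked from
unrounded transition probabilities cannot be determined from the printed
two-decimal matrix; we do not attempt to guess an unrounded matrix, and
these two cells are excluded from the hard reproduction tests. All other
cells, including every control-arm cell, match exactly. The in-text count
of 28 persons per 100 in severe/total/dead at year 4 is reproduced by
summing the rounded per-state cells (7 + 5 + 16), consistent with how the
count table itself is reported; the unrounded sum is 27.38.

Published incremental results (0.054 QALYs / −2,283 EUR for SM; 0.048 /
−2,091 for PV; booster 0.123 / −6,145) depend on undocumented spreadsheet
conventions and are reproducible only approximately; under the default
convention this implementation yields 0.0544 / −2,304 and 0.0498 / −2,182,
with booster-to-main ratios of 2.29 (QALYs) and 2.63 (costs) against the
reported "approximately 2.3 / 2.5". The reproduction tests therefore assert
bands (SM ΔQALY in [0.045, 0.065], Δcost in [−2,600, −1,900], ratios in
[2.0, 2.6] and [2.0, 2.8]) rather than equality, alongside exact goldens
for the quantities that are exactly derivable (risks, RRs, cost sheets,
count-table cells, the +32/+14 EUR cost-sensitivity shifts).

## Synthetic trials

`generate_arm()` draws one-year destination counts multinomially from a
true transition row at a given arm size — the exact statistical structure
of the source trial's follow-up table (all participants baseline-mild, one
multinomial row per arm). `generate_random_matrix()` samples transient rows
from a flat Dirichlet distribution, honouring the structural zero and the
absorbing death state, for property-style testing far from the shipped
fixture. A single seed controls each draw for bitwise reproducibility.

What the generator does *not* emulate: dropout and attrition, covariate
structure, individual longitudinal paths beyond one year, or sampling
uncertainty in the transition matrix itself. Passing recovery tests
therefore demonstrate that effect estimation is consistent under the
model's own sampling assumptions, not that the trial data satisfy them.

Problem sizes used in the stochastic test suite — 200 replicates of paired
arms at n = 10,000 for RR recovery (mean bias < 2%), a single n = 100,000
arm for risk convergence, and 1,000 random matrices propagated over 10
cycles for mass-conservation and absorption sweeps — were chosen so the
Monte-Carlo standard error is an order of magnitude below each asserted
tolerance.

## Numerical choices and degenerate inputs

* Row-sum and share-sum tolerance 1e-9; structural zeros and the absorbing
  row are checked exactly.
* `apply_effect()` re-validates its output and errors if an effect pushes
  any probability outside [0, 1]; RRs up to 2 are representable with the
  shipped mild row.
* Horizons below 1 year, negative costs, negative discount rates, empty
  configs and unknown config keys are rejected with named errors.
* Degenerate payoffs (all-zero utilities) and degenerate rows
  (probability 1 of staying) are supported and covered by tests.

## Known limitations

The model is a cohort-level simplification: no tunnel states, no
individual-level heterogeneity, a fixed 4-year horizon, and transition
probabilities taken as given from a two-decimal printed matrix rather than
re-estimated from source cohort data. Probabilistic sensitivity analysis
(parameter distributions, acceptability curves) is out of scope — the
analysis is deterministic by design, with one-way sensitivity variants
only.
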