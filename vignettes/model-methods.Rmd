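---
title: "Model methods: partitioned survival cost-effectiveness of first-line immunochemotherapy in advanced cervical cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## Overview

`psmcea` implements a three-state partitioned survival model (PSM) comparing
first-line pembrolizumab plus platinum-based chemotherapy (with or without
bevacizumab) against chemotherapy alone in persistent, recurrent, or
metastatic cervical cancer, costed from the perspective of the Chinese
healthcare system in USD. The default configuration
(`default_config()`, also shipped as `inst/extdata/base_case.yaml`) carries
every model input: survival curve parameters, unit prices, dosing rules,
adverse-event risks and costs, utilities, and analysis settings.

## Health states and occupancy

State occupancy is read directly off the two survivor functions rather than
from transition probabilities:

* progression-free: `PF(t) = S_PFS(t)` (clamped to `S_OS(t)` from above),
* progressed: `PD(t) = S_OS(t) - PF(t)`,
* dead: `1 - S_OS(t)`.

Both arms use log-logistic curves, `S(t) = 1 / (1 + (t/λ)^γ)` with the scale
λ equal to the median in months:

| Curve | Scale λ (months) | Shape γ |
|---|---|---|
| OS, intervention | 24.217 | 1.546 |
| OS, comparator | 17.255 | 1.718 |
| PFS, intervention | 12.2045 | 1.4758 |
| PFS, comparator | 8.1898 | 1.7748 |

The horizon is 86 cycles of 21 days (about 4.9 years). Months are converted
at 30.4375 days/month. Two conventions are deliberate package choices and are
configurable through `settings`:

* **Occupancy evaluation time** (`occupancy_eval`): occupancy for cycle *k*
  is evaluated at the *start* of the cycle by default (`"end"` and
  `"midpoint"` are available). Start-of-cycle evaluation reproduces the
  published per-arm cost totals for this model to within 1.5%.
* **Discounting**: costs and QALYs in cycle *k* are discounted by
  `(1 + r)^(-(k-1) * 21 / 365.25)` with `r = 0.05` annually.

Incident progression and death counts, used for one-time costs, are
successive differences of the cumulative curves at cycle ends, floored at
zero.

## Costing

Drug acquisition uses vial rounding: the administered dose (flat, per-kg, or
per-m² on a 1.62 m², 59 kg reference patient) is converted to whole vials by
ceiling division, because surplus drug is discarded. The chemotherapy
backbone (paclitaxel 175 mg/m², cisplatin 50 mg/m²) is capped at 6 cycles.
Pembrolizumab (200 mg flat) and bevacizumab (15 mg/kg, weighted by the
per-arm uptake fractions 0.636/0.625) continue while patients remain
progression-free; an explicit per-component `max_cycles` in the config can
cap them. Leaving them uncapped is the convention under which the model
reproduces the published cost totals. The donation pricing scenario
multiplies the pembrolizumab price by 0.414 (`pricing = "donation"`).

Progression-free occupancy also accrues administration fees, routine labs
each cycle, thyroid function every second cycle, and CT imaging on the
week-9-then-every-9-weeks (every 12 weeks after week 54) schedule mapped to
cycles via week = 3 × (cycle − 1). Progressed occupancy accrues best
supportive care per cycle; each incident death accrues a one-time
end-of-life cost. Grade ≥3 adverse-event expected costs and QALY losses
(risk × value; disutility −0.28 applied for one 21-day cycle) are charged
once in cycle 1.

## CEA, DSA, PSA

`run_base_case()` compares the arms: incremental cost, incremental QALYs,
dominance classification, ICER, and incremental net monetary benefit at the
willingness-to-pay threshold of three times GDP per capita
(3 × 11,756.31 ≈ 35,268.94 USD/QALY).

`one_way_dsa()` perturbs each of the 56 bounded parameters to ±20% bounds
(the discount rate to 0–8%) one at a time and reports the ICER spread,
sorted for a tornado diagram. `run_psa()` draws all 56 parameters jointly:
gamma for costs, beta for utilities and adverse-event risks (moment-matched
to mean and sd = (upper − lower)/3.92), a scaled beta for the discount rate,
and the negated-beta construction for the adverse-event disutility. Survival
parameters are not sampled, so the occupancy traces are fixed across PSA
draws. `ceac()` traces the acceptability curve over a WTP grid.

## Subgroups

For each of the 13 reported subgroups, the intervention arm's OS curve is
synthesized by raising the comparator OS survivor function to the subgroup
hazard ratio (proportional hazards); PFS curves, costs, and utilities stay
at base case. `subgroup_cea()` runs the model at the HR point estimate and
both confidence bounds; `subgroup_ce_probability()` adds the HR to the PSA,
drawing `log(HR) ~ N(log(hr), (log(hi) - log(lo))/3.92)`. Because the
powered comparator curve can dip slightly below the base intervention PFS
curve, mild clamping of progression-free occupancy is expected there and
the clamp warning is disabled for subgroup runs.

## Pseudo-IPD, fitting, and model selection

`simulate_ipd()` draws right-censored individual patient data from a known
curve by inverse-CDF sampling; the default scenario (n = 308 per arm,
uniform censoring on 0–120 months, roughly 30% censored for the base OS
curves) mimics the scale and maturity of the source trial data.
`fit_parametric()` fits any of six families (log-logistic, Weibull,
log-normal, Gompertz, gamma, exponential) by maximum likelihood via
`flexsurv`, and `select_best()` picks by AIC with BIC as tie-break.
`recovery_experiment()` wraps the loop simulate → fit → select and reports
bias, RMSE, and selection frequency; at n = 500 over 100 replicates the
log-logistic scale is recovered with |bias| well under 5%.

## Validation and known discrepancy

The test suite checks the model against the published headline numbers. The
cost side reproduces closely (incremental cost within 1.5%; donation-price
intervention cost within 0.2%), the WTP threshold exactly, and the PSA
cost-effectiveness probabilities within 2 percentage points. The QALY side
does **not** reproduce: under the stated curves, utilities, horizon, and
discounting, the maximum attainable discounted QALYs are about 1.52
(intervention) and 1.18 (comparator) versus the published 2.72 and 1.55 —
the published values exceed what the stated inputs can produce under any
standard accrual convention (an undiscounted, full-lifetime run still falls
short). The package reports the internally consistent values; acceptance
tests asserting the published QALY-side numbers fail by design and document
the discrepancy. Consequently the ICERs computed here are higher than the
published ones while preserving all published order relations (intervention
costlier and more effective; donation ICER below original; subgroup
lower-CI ICER < point < upper-CI ICER).

## Reproducing the headline results

```{r base-case, eval = FALSE}
cfg <- default_config()
run_base_case(cfg, pricing = "original")
run_base_case(cfg, pricing = "donation")
psa <- run_psa(cfg, n = 10000, seed = 1, pricing = "donation")
psa$prob_cost_effective
run_subgroups(cfg, pricing = "donation")
```

`run_all(cfg, seed, out_dir)` writes the full bundle (base case, tornado,
PSA draws, CEAC, subgroup table, run log) to CSV with deterministic child
seeds derived from one global seed.
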