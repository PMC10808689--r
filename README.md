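# psmcea

A partitioned survival cost-effectiveness model of first-line pembrolizumab
plus platinum-based chemotherapy (with or without bevacizumab) versus
chemotherapy alone in persistent, recurrent, or metastatic cervical cancer,
from the perspective of the Chinese healthcare system.

Health-state occupancy (progression-free / progressed / dead) is derived
directly from log-logistic overall-survival and progression-free-survival
curves over 86 three-week cycles with 5% annual discounting. On top of the
core model the package provides:

* **Costing** with vial-rounded drug acquisition (body-surface-area and
  weight-based dosing), administration, scheduled monitoring and imaging,
  one-time adverse-event burden, supportive and end-of-life care, and a
  charitable-donation pricing scenario (pembrolizumab at 41.4% of list
  price).
* **CEA outputs**: incremental costs and QALYs, dominance classification,
  ICER, and net monetary benefit at a WTP threshold of three times GDP per
  capita (≈ 35,268.94 USD/QALY).
* **Sensitivity analyses**: a 56-parameter one-way DSA (tornado) and a
  probabilistic sensitivity analysis with gamma-distributed costs,
  beta-distributed utilities and adverse-event risks, and
  cost-effectiveness acceptability curves.
* **Subgroup analyses** for 13 reported subgroups via proportional hazards
  applied to the comparator OS curve, including a probabilistic
  cost-effectiveness probability with a lognormal hazard-ratio draw.
* **Pseudo-IPD tooling**: a seeded simulator of censored individual patient
  data, Kaplan-Meier estimation, maximum-likelihood fitting of six
  parametric survival families (via `flexsurv`) with AIC/BIC model
  selection, and a parameter-recovery experiment harness.

See `vignettes/model-methods.Rmd` for the modeling conventions, the PSA
distribution construction, and a discussion of which published quantities
the model does and does not reproduce (the cost side reproduces within
1.5%; the published QALY totals are not attainable from the stated inputs,
so the package reports the internally consistent values).

## Worked example

```r
library(psmcea)

cfg <- default_config()          # full Table-style parameter set

res <- run_base_case(cfg, pricing = "original")
res
#> <cea_result> dCost 136,434.6 USD, dQALY 0.348 -> ICER 391,700.5 USD/QALY

base_case_table(res)
#>            arm total_cost total_qalys     icer
#> 1 intervention  161410.58   1.5239207       NA
#> 2   comparator   24975.93   1.1756070       NA
#> 3  incremental  136434.65   0.3483137 391700.5

run_base_case(cfg, pricing = "donation")
#> <cea_result> dCost 61,853.13 USD, dQALY 0.348 -> ICER 177,578.8 USD/QALY

psa <- run_psa(cfg, n = 2000, seed = 42, pricing = "donation")
psa$prob_cost_effective
#> [1] 0

tab <- run_subgroups(cfg, pricing = "donation")
head(tab[, c("label", "hr", "icer_point", "status_at_upper")], 4)
#>            label   hr icer_point status_at_upper
#> 1  Age <65 years 0.64   155961.5            icer
#> 2 Age >=65 years 0.88   313650.3       dominated
#> 3          White 0.68   171972.5            icer
#> 4      Non-White 0.70   180964.0            icer
```

`run_all(cfg, seed = 1, out_dir = "out")` writes the full analysis bundle
(base case, tornado, PSA draws, CEAC, subgroup table, run log) as CSV, with
all stage seeds derived deterministically from the one global seed. A thin
command-line wrapper lives at `inst/scripts/psmcea.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/psmcea.R", package="psmcea"))')" \
  run --config inst/extdata/base_case.yaml --seed 42 --out out/
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "psmcea", load_package = "installed")'
```

`tests/testthat/test-acceptance.R` checks the model against published
headline values. The cost-side, threshold, probabilistic, ordering, and
property assertions pass; the assertions on the published QALY totals (and
the ICERs that inherit them) fail by design and document a reproducibility
gap analyzed in the methods vignette.

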