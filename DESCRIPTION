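Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Analysis of First-Line
    Immunochemotherapy in Advanced Cervical Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state partitioned survival model for the cost-effectiveness
    of first-line pembrolizumab plus platinum-based chemotherapy (with or
    without bevacizumab) against chemotherapy alone in persistent, recurrent,
    or metastatic cervical cancer, from the perspective of the Chinese
    healthcare system. Health-state occupancy is derived from log-logistic
    overall-survival and progression-free-survival curves over 86 three-week
    cycles; the package computes discounted costs and quality-adjusted life
    years per arm, incremental cost-effectiveness ratios, one-way deterministic
    and probabilistic sensitivity analyses with cost-effectiveness
    acceptability curves, and proportional-hazards subgroup analyses. A
    pseudo individual-patient-data simulator and parametric fitting with
    AIC/BIC model selection across six survival families make the curve
    selection stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
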