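Package: osteohta
Title: Health Economic Modelling of Antiosteoporotic Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the health-technology assessment of antiosteoporotic
    drugs in postmenopausal women. Provides a seven-state, six-month-cycle
    Markov cohort model for lifetime cost-effectiveness analysis with
    probabilistic sensitivity analysis and cost-effectiveness acceptability
    curves; a three-component budget-impact model (demographic projection,
    disease model, market-share technology prediction) comparing scenarios
    with and without denosumab; a hospitalization burden-of-illness
    calculator based on DRG tariffs; and deterministic generators for the
    background inputs the models need (all-cause female life tables,
    age-specific baseline fracture hazards, population projections).
    All user-facing functions take and return data frames so analyses
    compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
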