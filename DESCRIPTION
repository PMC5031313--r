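Package: damcost
Title: State-Level Economic Burden of Disease-Associated Malnutrition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the state-level direct medical cost of
    disease-associated malnutrition (DAM). Classifies malnutrition from
    anthropometry and serum albumin (Hamwi ideal-body-weight rule),
    estimates disease and malnutrition-within-disease prevalence from
    complex-survey microdata with design-based standard errors, applies an
    attributable-cost equation over states, diseases and demographic
    cells, and quantifies uncertainty with a design-preserving Rao-Wu
    rescaling bootstrap plus Monte Carlo cost-parameter draws. Ships a
    synthetic-survey generator with known ground truth so the whole
    pipeline is testable without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
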