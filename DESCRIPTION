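Package: cartsim
Title: Tumor and CAR-T Cell Dynamics Under Impulsive Dosing Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic simulation of glioblastoma growth under chimeric
    antigen receptor (CAR) T-cell therapy.  Implements three coupled
    population models -- a logistic tumor/CAR-T base model, an extension
    with therapy-induced resistance, and a delay-differential extension
    with a CAR-T activation lag -- integrated by fixed-step Runge-Kutta
    schemes with impulsive (instantaneous) dose administrations.  Ships
    the clinical dosing protocols targeting IL13R-alpha-2, HER2/CMV and
    EGFRvIII as presets, body-surface-area dosing via the Haycock
    formula, trajectory endpoints (time to progression, threshold
    crossings, fixed-day tumor burden), dose/interval sweep utilities,
    and Morris elementary-effects sensitivity screening of both extended
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
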