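Package: pahrisk
Title: Probabilistic Inhalation Cancer-Risk Assessment for PM2.5-Bound PAHs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the probabilistic health-risk assessment of polycyclic
    aromatic hydrocarbons (PAHs) bound to fine particulate matter (PM2.5).
    Computes benzo[a]pyrene toxic-equivalent concentrations (BaP-TEQ) from
    congener tables using toxic equivalency factors, screens emission sources
    with diagnostic congener ratios, and propagates exposure-factor
    distributions through Monte-Carlo simulations of daily intake (DI) and
    incremental lifetime cancer risk (ILCR), with partial-correlation
    sensitivity analysis and two-dimensional (variability/uncertainty)
    Monte-Carlo analysis of the cancer-slope-factor truncation bound. Ships a
    seeded synthetic-data generator emulating multi-city seasonal congener
    concentrations and exposure-time surveys so the full pipeline runs without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
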