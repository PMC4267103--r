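Package: listlite
Title: Deterministic Multi-Cause Child Mortality Modelling for Community
    Case Management Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transparent, deterministic multi-cause model of under-five
    mortality that converts changes in health-intervention coverage into
    cause-specific deaths averted without double counting, attributes lives
    saved to individual interventions (preventive interventions first across
    the continuum of care, then curative), and isolates the impact of a
    community case management (iCCM) program by comparing an observed
    scenario against a facility-only counterfactual in which community
    delivery is frozen at its baseline level. Includes seeded synthetic
    generators of configurations and survey-style coverage tables so all
    analyses and tests run without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
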