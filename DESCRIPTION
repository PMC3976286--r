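Package: lungtrace
Title: Individual-Level Natural History and Detection of Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microsimulation of the natural history of lung cancer at the
    individual level: smoking-dependent tumor onset through a two-stage clonal
    expansion (TSCE) model, exponential primary-tumor growth with
    gamma-distributed growth rates, detachment-driven hazards of nodal and
    distant metastasis, competing-mode size-dependent detection on a yearly
    cycle, calendar-time birth-cohort population simulation, and
    simulation-based least-squares calibration of the nine progression and
    detection parameters to joint tumor-size by stage distributions via
    Nelder-Mead.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    yaml,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
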