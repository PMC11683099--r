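Package: ccdm
Title: Coupling Coordination Analysis of Health Resource Allocation and
    Economic Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring how well two regional subsystems develop
    together, built around the coupling coordination degree model (CCDM)
    used in health-systems research. Provides entropy-weighted composite
    evaluation indices for a health-resource-allocation subsystem and an
    economic-development subsystem, the relative development degree with
    its 0.8/1.2 classification thresholds, coupling degree, coordination
    index and coupling coordination degree with a ten-grade scheme, and a
    two-way fixed-effects panel regression of the log coordination degree
    on logged driver variables together with a diagnostic battery (panel
    unit-root tests, a residual-based cointegration check, poolability F,
    Breusch-Pagan LM and a robust Hausman test). A synthetic panel
    generator with known ground truth makes every stage testable without
    access to statistical-yearbook data.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
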