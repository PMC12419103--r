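Package: cowflow
Title: Circle-of-Willis Hemodynamics with Doppler Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Patient-specific steady simulation of cerebral blood flow in the
    Circle of Willis and the statistics used to validate simulated velocities
    against transcranial color-coded duplex sonography (TCCD). Implements the
    Casson yield-stress rheology of blood with its closed-form pipe-flow
    solution, a desk-scale axisymmetric finite-volume pressure-correction
    solver for single vessel segments, a reduced-order nonlinear network
    solver for Circle-of-Willis anatomy driven by Doppler inlet velocities
    and pressure outlets, a synthetic stroke-cohort generator with a TCCD
    measurement-noise model (including angle-correction underestimation), and
    agreement statistics: intraclass correlation (two-way, absolute
    agreement), Pearson correlation, Bland-Altman with normality-gated
    percentile limits, and per-artery difference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
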