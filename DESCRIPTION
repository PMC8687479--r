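Package: tepflow
Title: TMS-Evoked Potential Reactivity, Cluster Permutation Testing, and
    Mental-Health Regression Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing EEG responses to single-pulse transcranial
    magnetic stimulation (TMS) as predictors of psychological resilience.
    Implements global mean field amplitude and z-scored local region-of-interest
    reactivity measures for TMS-evoked potentials (TEPs), trapezoidal
    area-under-curve scoring, resilient/vulnerable classification from
    longitudinal PHQ-4 trajectories, cluster-corrected permutation testing of
    group differences on evoked time-series, and Box-Cox transformed multiple
    regression with nested-model comparison and variance decomposition. A
    synthetic cohort generator produces evoked time-series and questionnaire
    tables with the statistical structure the analysis assumes, so the full
    pipeline can be exercised and validated without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    car,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    nortest,
    yaml
Config/testthat/edition: 3
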