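Package: cetacond
Title: Morphometric Body Condition Indices and Blubber Cortisol Modelling
    for Small Cetaceans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for evaluating body condition in small cetaceans from
    strandings data. Computes ten morphometric condition indices (simple
    ratios, Fulton's K, Quetelet's index, relative condition, the residual
    index and the scaled mass index), fits linear and nonlinear mass-length
    allometry with size-independence diagnostics, and ranks the indices with
    a ground-truthing framework based on all-subsets information-criterion
    model selection and partial eta-squared effect sizes. A second tool
    chain quantifies blubber cortisol from competitive immunoassay plates
    (four-parameter logistic calibration, tissue-concentration correction,
    intra- and inter-assay CV quality gates) and models concentrations with
    gamma log-link mixed and fixed-effect models over body site, blubber
    layer and individual covariates. A calibrated synthetic-data generator
    provides morphometric, cortisol and assay-plate datasets with the
    statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    emmeans,
    glmmTMB,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
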