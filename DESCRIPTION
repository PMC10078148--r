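Package: fireburden
Title: Deforestation, Fire, Smoke and Health Burden Modelling for the Amazon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how deforestation and climate drive vegetation
    fire in the Brazilian Amazon and what reduced deforestation would mean
    for smoke exposure and public health. The package generates synthetic
    gridded climate, deforestation, land-cover, fire-detection, emission,
    particulate-matter and demographic inputs with a known generative model;
    builds the monthly cell-level feature panel used for fire-count
    regression; trains and evaluates gradient-boosted-tree and neural-network
    ensembles under a chronological leave-one-year-out protocol; estimates
    fire sensitivity to temperature, precipitation and deforestation by
    incremental perturbation; constructs counterfactual deforestation and
    climatological-climate scenarios with pattern-preserving rescaling;
    scales fire emissions by predicted fire-count ratios; and computes
    PM2.5-attributable deaths, years of life lost, years lived with
    disability and disability-adjusted life years with the Global Exposure
    Mortality Model (GEMM) hazard function and the subtraction method for
    averted burden.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    ranger,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'fireburden-package.R'
    'gridded-field.R'
    'world-config.R'
    'synthetic-world.R'
    'features.R'
    'fire-models.R'
    'attribution.R'
    'scenario.R'
    'health.R'
    'io.R'
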