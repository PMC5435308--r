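Package: hdsland
Title: Hierarchical Distance Sampling for Landscape-Scale Small Mammal Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits hierarchical distance-sampling models (multinomial-Poisson
    mixture likelihood) to point- and line-transect survey data with
    log-linear covariates on both abundance and the detection-function
    scale, following the workflow used for landscape-scale density
    estimation of sciurid and leporid prey species: quantile truncation of
    distances, half-normal and hazard-rate detection functions, a two-step
    covariate screening and candidate-set model selection with AICc/QAICc,
    parametric-bootstrap goodness-of-fit with a Freeman-Tukey statistic and
    over-dispersion correction, site-level nonparametric bootstrap of
    occasion densities, and raster-based spatial prediction of density with
    delta-method standard errors. Includes a synthetic-data module that
    simulates spatially autocorrelated covariate landscapes, the nested
    transect design, and distance-sampling observations with known truth
    for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
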