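Package: noiseLUR
Title: Land Use Regression Modelling of Outdoor Noise Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building land use regression (LUR) models of outdoor
    environmental noise. Converts raw one-second A-weighted sound level
    logger series into cleaned period metrics (Lday, Levening, Lnight,
    LAeq24h, Lden), derives candidate geographic predictors (road lengths,
    inverse distances, household density, land-use areas, vegetation index)
    within circular buffers around monitoring sites, and fits a supervised
    stepwise LUR model with a sign-constrained univariate screen, a
    correlation-gated forward selection, backward pruning, a challenge step
    and a final augmentation step. A synthetic-data module generates
    settlement layouts, predictor layers and raw level series with known
    ground truth so that every stage of the pipeline can be validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'acoustics.R'
    'geometry.R'
    'gis.R'
    'io.R'
    'lur.R'
    'synthetic.R'
    'pipeline.R'
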