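Package: surfaceomics
Title: Expressed-Surfaceome Inference from Normalized Transcriptomic Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the "expressed surfaceome" of a transcriptomic dataset by
    empirical-CDF quantile ranking of normalized expression, quartile tiering,
    and intersection of top-quartile cell-surface genes across datasets.
    Provides functional-class and glycosylation-motif breakdowns of the
    resulting gene sets, per-gene differential screening by HPV status,
    contingency tests for motif enrichment between expression tiers,
    drug-target cross-referencing summaries per protein class, and clinical
    association statistics including median-dichotomized Kaplan-Meier survival
    comparisons. A synthetic-data generator produces complete input bundles
    (annotation catalogue, expression matrices, drug map, clinical and
    immunohistochemistry tables) with the statistical structure the analysis
    assumes, plus exact fixtures reproducing published contingency and
    druggability summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'clinical.R'
    'differential.R'
    'druggability.R'
    'expressed.R'
    'fixtures.R'
    'io.R'
    'pipeline.R'
    'simulate.R'
    'summarize.R'
    'surfaceomics-package.R'
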