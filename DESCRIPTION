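Package: senescore
Title: Cellular Senescence Gene-Expression Composite Scores and Aging-Outcome Associations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes bulk RNA-seq composite scores for cellular senescence
    (canonical senescence pathway, senescence-initiating pathway, senescence
    response pathway, their deduplicated summary, and a SenMayo-style SASP
    list) from relative-log-expression-normalized log2 counts-per-million,
    and links the scores to socio-behavioral factors and aging-related
    outcomes through a survey-weighted regression grid with standardized
    coefficients, Benjamini-Hochberg false-discovery-rate adjustment, and
    k-fold cross-validation. Includes a negative-binomial synthetic-cohort
    generator with a latent senescence factor and a truth record for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, RNASeq, Normalization, Regression, Epigenetics
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'association.R'
    'cohort-config.R'
    'io.R'
    'methods.R'
    'model-grid.R'
    'normalize.R'
    'pipeline.R'
    'scores.R'
    'synthetic-counts.R'
    'synthetic-genesets.R'
    'synthetic-phenotypes.R'
    'utils.R'
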