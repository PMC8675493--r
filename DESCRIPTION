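Package: scdrugsens
Title: Drug-Response Heterogeneity Scoring for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies drug-response heterogeneity in single-cell RNA-seq
    data. Every cell is scored against bidirectional (UP/DN) drug or
    functional gene signatures; per-signature scores are rescaled to [0,1]
    and summarised by a switch point that measures how homogeneously the
    population responds. Score matrices can be cleaned of nuisance
    covariates (library size, cell cycle) by KNN imputation and linear-model
    residuals, clustered into therapeutic clusters, and used to rank drugs
    that differentially target chosen cell groups. Includes builders for
    perturbation- and sensitivity-style signatures from bulk pharmacogenomic
    tables, a decile-based drug-background selector, and a synthetic-data
    generator with planted therapeutic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Matrix,
    FNN,
    igraph,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
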