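Package: tregstrat
Title: Treg-Enriched Tumor Subtype Discovery from Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative multi-omics subtype discovery centred on regulatory
    T cell (Treg) driven immunosuppression. Provides layer-wise preprocessing
    (missingness filtering, K-nearest-neighbour imputation, min-max scaling,
    top-variance feature selection), autoencoder and PCA latent embeddings,
    subsampled consensus K-means with PAC-based model selection, cluster
    characterization (signature scoring, GSEA, over-representation analysis,
    nonparametric group tests, exhaustion-marker panels), a multi-criteria
    rule for naming the most Treg-enriched cluster, and preclinical efficacy
    analytics (tumor growth inhibition, normalized AUC, Highest Single Agent
    and Bliss independence synergy, two-way ANOVA). A synthetic multi-omics
    and tumor-growth generator with planted ground truth supports end-to-end
    testing without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea
Config/testthat/edition: 3
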