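Package: ubiScreen
Title: Pan-Cancer Proteomic Screening of E3 Ligase Regulatory Patterns and
    Degradative Ubiquitination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-omics toolkit for characterizing E3 ubiquitin ligase and
    deubiquitinase regulation across tumor/normal proteomic cohorts. Provides
    missing-value filtering and ensemble imputation for mass-spectrometry
    abundance matrices, rank-based differential expression with
    Benjamini-Hochberg control, signed-scaled fold-change atlases with Ward
    clustering and hypergeometric over-representation, shared-nearest-neighbor
    sample clustering with JackStraw-selected principal components,
    E3-substrate Spearman correlation screens against random backgrounds, a
    three-criterion multi-omics screen for substrates under degradative
    ubiquitination, a from-scratch signaling pathway impact analysis engine,
    and proteome-based prognosis tools (Cox models, maximally selected rank
    statistics, biweight midcorrelation). A synthetic multi-omics cohort
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
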