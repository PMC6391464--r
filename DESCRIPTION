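Package: metaboScreen
Title: Untargeted LC-HRMS Metabolomics for In Vitro Drug Metabolite Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end untargeted metabolomics workflow for discovering in
    vitro biotransformation products of drugs incubated with pooled human liver
    microsomes. Provides a ground-truth simulator for centroided LC-HRMS
    incubation studies (dose groups, pooled QC injections, injection-order
    drift, isotopologues, adducts and in-source artifacts), chromatographic
    peak detection and cross-sample feature grouping, fold-change and Welch
    t-test significance filtering, QC-anchored linear drift correction,
    multivariate diagnostics (PCA, t-SNE, hierarchical clustering), and
    rule-based annotation of significant features as isotopes, adducts,
    artifacts, impurities, isomers or metabolites via catalogued
    biotransformation mass shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    xml2,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metabolomics, MassSpectrometry, Preprocessing, BatchEffect,
    Software
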