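Package: sexdim
Title: Sex-Dependent Differential Expression and Regulatory Network
    Analysis for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for dissecting sex-dependent molecular changes in
    case-control single-cell RNA-seq studies, with a companion proteomics
    layer. Provides per-stratum (cell type by sex) Poisson generalized
    linear model likelihood-ratio differential expression with
    Benjamini-Hochberg correction; classification of features into
    sex-neutral, sex-specific, and sex-dimorphic patterns; hypergeometric
    over-representation analysis with a term-level sex-specificity
    criterion; ligand-receptor communication filtering; genetic-algorithm
    construction of phenotype-specific signed gene regulatory networks
    with perturbagen and mediator ranking; empirical-Bayes moderated
    protein differential abundance; sex-stratified Spearman covariate
    correlations; and a synthetic-data generator with planted effects so
    the whole pipeline is testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    limma,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
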