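Package: wbatlas
Title: Whole-Body Single-Cell Atlas Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-body single-cell RNA-seq atlases of
    small metazoans such as adult Caenorhabditis elegans. Aggregates labeled
    count matrices into per-cell-type scaled-TPM profiles with bootstrap
    confidence intervals and robust-expression calls; models gene-detection
    saturation per cell type with a three-parameter log-logistic curve to
    estimate transcriptome coverage; scores housekeeping-gene candidates by
    moment skewness of percent-cells-expressing and by the Gini coefficient of
    expression across cell types; infers transcription-factor activity per cell
    type by clustering ChIP-seq peaks along the genome, assigning clusters to
    target genes by TSS proximity and fitting L1-regularized regressions of
    expression on normalized binding signal; and scores ligand-receptor
    mediated cell-cell communication with a permutation null, summarizing
    significant interactions by non-negative canonical polyadic tensor
    decomposition into communication signatures. Includes a synthetic-data
    generator with planted ground truth (housekeeping genes, TF-to-cell-type
    activity, sender/receiver signatures) so every stage can be validated by
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    minpack.lm,
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
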