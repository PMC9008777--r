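Package: EndoCt
Title: Endogenous Control Discovery and Normalization Benchmarking for
    Circulating miRNA Ct Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for selecting endogenous control (housekeeping) microRNAs
    from array-based RT-qPCR profiling of circulating miRNAs. Implements
    quality control for Ct data (amplification-score and Cq-confidence
    filters, sample and miRNA missingness filters, non-detect imputation),
    five normalization strategies (global mean with and without imputation,
    restricted mean-centering, quantile, endogenous control), per-miRNA
    standard-deviation benchmarking of normalizers, four reference-stability
    algorithms (geNorm, NormFinder, BestKeeper, comparative delta-Ct) with a
    comprehensive geometric-mean-of-ranks ordering, combination-control
    evaluation, covariate (age/sex) sensitivity analysis, and a synthetic Ct
    data generator with detection-limit censoring for validating the whole
    pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Normalization, QualityControl, qPCR, miRNA, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'ct_io.R'
    'normalize.R'
    'pipeline.R'
    'qc.R'
    'sensitivity.R'
    'simulate.R'
    'stability.R'
    'utils.R'
    'variability.R'
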