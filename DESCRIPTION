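Package: cqstab
Title: Reference Gene Stability and Normalization Validation for RT-qPCR
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for selecting and validating reference (housekeeping) genes
    for RT-qPCR normalization from quantification-cycle (Cq) data. Implements
    five stability estimators (coefficient of variation on linear-scale
    expression, geNorm M values with pairwise-variation analysis, the
    NormFinder variance-decomposition model, the BestKeeper index, and the
    comparative delta-Ct method), geometric-mean consensus ranking across
    estimators, the geNorm rule for the optimal number of reference genes,
    multi-reference normalization factors with statistical validation of
    candidate reference sets against genes of interest, and evaluation of
    reference genes under nutrient stress. Includes a seeded synthetic Cq
    generator with passage, lysate and technical variance components and
    planted instabilities for benchmarking the estimators on data with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
biocViews: GeneExpression, Normalization, qPCR, Software
RoxygenNote: 7.3.3
Collate: 
    'cqstab-package.R'
    'AllGenerics.R'
    'utils.R'
    'CqSet-class.R'
    'StabilityTable-class.R'
    'cq-io.R'
    'describe.R'
    'bestkeeper.R'
    'consensus.R'
    'deltact.R'
    'genorm.R'
    'normfinder.R'
    'synthetic.R'
    'validation.R'
    'report.R'
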