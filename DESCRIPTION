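Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Ranks candidate reference (housekeeping) genes for RT-qPCR
    normalization from a matrix of quantification-cycle (Ct/Cq) values.
    Implements the four standard stability algorithms - geNorm (pairwise
    M values, stepwise exclusion and the V(n/n+1) pairwise variation used
    to choose how many reference genes to combine), NormFinder (model-based
    variance estimation on log quantities), BestKeeper (descriptive
    statistics on raw Ct, SD-based exclusion, pairwise and index
    correlations) and the comparative delta-Ct method - together with a
    RefFinder-style consensus that aggregates the four rankings by the
    geometric mean of ranks. Ships a published 32-sample, 10-gene Ct
    data set measured in peripheral blood mononuclear cells of six
    trans-Himalayan livestock species, a synthetic Ct generator for
    parameter-recovery experiments, and batch reporting to delimited
    tables.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
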