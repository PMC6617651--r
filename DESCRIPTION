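Package: methsig
Title: Blood DNA Methylation Signatures for Variant Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives blood DNA-methylation (DNAm) signatures from Illumina
    EPIC-style beta-value matrices and uses them to classify sequence
    variants as pathogenic or benign. Implements probe quality-control
    filters, reference-based blood cell-type deconvolution, covariate-
    adjusted differential methylation with empirical-Bayes variance
    moderation, signature selection, a correlation-difference episignature
    score, range-overlap decomposition of partial (mosaic) signatures,
    bootstrap differentially methylated region detection, and
    hypergeometric gene-set enrichment. Ships a synthetic-data generator
    that emulates the statistical structure of a case-control methylation
    study so the whole workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    quadprog,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
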