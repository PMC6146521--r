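Package: metlink
Title: Linking Somatic Mutation Burden to Transcriptome Remodelling in
    Matched Tumour Cohorts
Version: 0.1.0
Authors@R:
    person("Met", "Link", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for matched normal / multi-region primary
    tumour / metastasis sample sets: a somatic-variant filter cascade
    (allele fraction, read depth, per-strand support, population allele
    frequency), metastasis-exclusive variant set algebra, mutation-spectrum
    summaries (transition/transversion, C:G vs A:T pairs), median-of-ratios
    expression normalization with per-pair fold-change rankings, and a
    rank-based two-sample Kolmogorov-Smirnov association between mutation
    classes and expression changes, assembled into a sample-by-class
    association matrix.  Includes a synthetic-cohort generator with a known
    mutation-to-expression coupling for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
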