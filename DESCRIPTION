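Package: strokeTriage
Title: Blood Transcriptome Stroke Triage with Gaussian Hidden Markov Model Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression and correlation-based transcript selection
    followed by Gaussian-emission hidden Markov model panel classifiers for
    admission whole-blood RNA triage of suspected stroke: hemorrhagic versus
    ischemic stroke versus stroke mimic, thrombolysis-window (within 3.5 hours
    of onset) eligibility, and NIHSS severity stratification. Includes a
    negative-binomial synthetic whole-blood transcriptome generator so the
    entire pipeline is testable end-to-end, exhaustive 3-5 transcript panel
    enumeration with deterministic representative-panel selection, posterior
    probability threshold optimization by Youden's J, and a hierarchical
    triage cascade with leakage-free train/validation evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, Classification, RNASeq, GeneExpression
RoxygenNote: 7.3.3
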