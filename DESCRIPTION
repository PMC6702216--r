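Package: itrfun
Title: Classification and Functional-Likelihood Prediction of Intergenic
    Transcribed Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing intergenic transcribed regions (ITRs)
    detected in plant RNA-seq experiments: merging and priority-based
    classification of assembled transcript fragments against gene and
    pseudogene annotation, flagging of repetitive and protein-coding
    fragments, empirical-null cross-species conservation calling,
    expression-conservation statistics with breadth-matched controls,
    synteny-based duplicate retention analysis after whole-genome
    duplication, construction of a 44-feature evolutionary and biochemical
    predictor table (transcription, conservation, chromatin, DNA
    methylation), and a balanced-ensemble random-forest model that scores
    each region with a functional likelihood and classifies it under
    calibrated false-positive / false-negative thresholds. A synthetic-data
    module generates every pipeline input with known ground truth so the
    full analysis can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    ranger,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
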