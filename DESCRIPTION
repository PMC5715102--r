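Package: brainAgeNet
Title: Co-Expression Network Analysis of Brain Aging Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-wide analysis of aging in post-mortem human
    brain: detection filtering of transcripts against per-sample intronic
    background, signed weighted co-expression network construction with
    topological overlap, module detection and eigengene summaries, association
    of modules and transcripts with age and technical covariates,
    marker-regression (PSEA-style) cell-type deconvolution with
    neuron-corrected age associations, cross-dataset validation of
    age-association profiles, and hypergeometric gene-set over-representation
    for modules. Includes a synthetic cohort generator that plants known
    co-expression modules, age effects and age-drifting cell-type proportions
    so every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
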