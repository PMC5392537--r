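Package: methage
Title: DNA Methylation Age Prediction with Generalised Regression
    Neural Networks and Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building and validating chronological age predictors
    from DNA methylation beta values. Implements a synthetic whole-blood
    cohort generator with configurable age trends, batch structure, twin
    pairs and disease perturbations; a bisulfite PCR amplicon panel model
    with in-silico bisulfite PCR; a paired-end bisulfite amplicon read
    simulator and per-CpG C/T methylation caller with conversion-control
    correction and coverage filtering; standard-curve and cross-dataset
    beta-value normalization; per-marker regression screening, forward
    stepwise selection and a multiple-linear-regression baseline; a
    generalised regression neural network (GRNN) age model with staged
    split optimization, replicate variability and variable-removal
    sensitivity analysis; and an end-to-end pipeline from FASTQ reads to
    age predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
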