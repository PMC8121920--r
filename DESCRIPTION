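Package: ascap
Title: Allele-Specific Chromatin Accessibility Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of allele-specific DNA accessibility at
    heterozygous variants in F1 hybrid genomes: filtered allele-specific read
    counting at single-nucleotide variants in DNase I hypersensitive sites,
    beta-binomial tests of allelic imbalance with Storey q-value FDR control
    at multiple pooling levels, cross-condition sharing of imbalance (1 - pi0),
    per-position transcription-factor motif sensitivity profiles, a two-stage
    logistic variant-impact score (global genomic-context model, per-TF models,
    lasso-penalized combiner), and correlation of allelic accessibility with
    allelic transcript levels as a function of distance to the TSS. Includes a
    synthetic-data generator reproducing the statistical structure of such
    studies so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
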