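Package: olfscreen
Title: Olfactory Epithelium Transcriptome Screening and Olfactory Receptor
    Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for bulk RNA-seq analysis of olfactory
    (nasal sensory) epithelium. Implements a tissue-overexpression screen
    with a negative-binomial exact test, median-of-ratios normalization,
    respiratory-contamination filtering and cross-species (mouse) rescue;
    olfactory receptor (OR) repertoire expression statistics including
    rank and cumulative-skew curves; a matched-distribution resampling
    test for inter-individual variability of OR expression; curation of
    assembled OR transcript models with detection of aberrant
    start-codon-skipping isoforms; and TSS-anchored positional profiling
    of transcription-factor binding motifs in OR promoters. A synthetic
    data generator with planted ground truth emulates every input so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
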