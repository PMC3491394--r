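Package: sitefun
Title: Functional Analysis of Transcription Factor Binding Sites in Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and functionally characterising transcription
    factor binding sites (TFBSs) on promoters. Provides position weight matrix
    (PWM) construction and locally-conditioned log-odds scanning, ROC/AUC
    evaluation of PWMs against length-matched genomic background, design of
    site-abolishing mutations that avoid creating binding sites for other
    factors, statistics for replicated luciferase reporter assays (Welch t
    tests with a global Benjamini-Hochberg correction and FDR-based functional
    calls), and comparisons of functional site classes by conservation,
    TSS distance, motif information content, homotypic clustering, secondary
    motif enrichment and CpG content. A synthetic-data generator emulates the
    full study design (planted motifs, ChIP-seq-like peaks, conservation
    tracks, nested replicate luminosities) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
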