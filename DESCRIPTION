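Package: methylbind
Title: Integration of Whole-Genome Bisulfite Methylomes with Transcription
    Factor ChIP-Seq Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies DNA methylation at transcription factor ChIP-seq
    peaks and at motif-relocated binding sites by integrating per-cytosine
    whole-genome bisulfite sequencing calls with narrowPeak intervals.
    Classifies peaks and binding sites by methylation level, discovers and
    scans position weight matrices to relocate binding sites inside peaks,
    reconstructs methylation-aware motifs over an extended {A,C,G,T,E}
    alphabet where E marks methylated CpG cytosines, profiles methylation
    around binding-site centers, annotates binding by chromatin state,
    and measures cross-cell-type conservation of binding stratified by
    methylation. Ships a synthetic-data generator (genomes with CpG
    islands, binomially sampled methylomes, planted motif occurrences,
    multi-cell occupancy plans, block segmentations) so every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
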