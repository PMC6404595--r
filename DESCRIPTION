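Package: mitoedit
Title: Detection and Comparison of C-to-U RNA Editing Sites in Plant
    Mitochondrial Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects C-to-U RNA editing sites in plant mitochondrial
    protein-coding transcripts from RNA-seq read alignments. Builds
    per-position base pileups from SAM/BAM, calls editing sites with
    coverage, count, frequency and binomial error-probability filters,
    quantifies editing extent, annotates codon and amino-acid consequences
    under the plant mitochondrial genetic code, flags genes contaminated by
    reads from diverged nuclear paralogs, compares sites across samples or
    species with a coverage gate, and classifies genomic C/T polymorphisms
    that abolish or mimic editing sites. Includes a read simulator with
    known per-site editing extents, genomic-DNA contamination and paralog
    reads, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
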