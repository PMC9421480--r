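Package: linctk
Title: Identification, Annotation and Comparative Analysis of Long
    Intergenic Noncoding RNAs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for confidence classification and functional
    annotation of long intergenic noncoding RNAs (lincRNAs) in plant genomes.
    Implements hierarchical confidence filtering of candidate transcripts
    (long-read support, exon structure, length, multi-project expression),
    harmonization of pre-existing annotations, tissue-specificity (tau) and
    context-specific expression calls, stress-response set construction,
    phylogenetic node-of-conservation assignment, synteny-based detection of
    sequence-divergent conserved loci, whole-genome-duplication-aware gene
    family dynamics, motif conservation calls on multiple sequence
    alignments, and neighbor expression correlation analysis.  Ships a
    synthetic-data generator that plants machine-readable ground truth so
    every stage can be validated end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
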