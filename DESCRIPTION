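Package: noirss
Title: Barcode-Based Error Elimination and Molecule Counting for TCR Beta
    Repertoire Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a molecular-barcode (UMI) consensus pipeline for
    T-cell receptor beta chain (TCRB) CDR3 repertoire sequencing: reads are
    demultiplexed by sample index, grouped by 12-base random barcode tags,
    erroneous tags are detected from the tag-length spectrum and removed by
    a read-count threshold, and one consensus sequence per molecule is built
    by multiple alignment with a per-column majority rule. Consensus
    molecules are annotated against a germline V/J reference, the CDR3
    junction is extracted between the conserved cysteine and phenylalanine
    anchors, and unproductive rearrangements are discarded. Repertoire
    statistics include abundance-based coverage estimation (ACE) of
    repertoire size, rarefaction, abundance classes, V/J segment usage and
    cross-sample clonotype sharing. A ground-truthed V(D)J read simulator
    with an indel-dominant error model makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    BiocGenerics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
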