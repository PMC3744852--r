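Package: clipcnv
Title: Single-Base CNV Breakpoint Detection from Soft-Clipped Split Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates deletion and tandem-duplication breakpoints at
    single-base resolution by pairing soft-clipped reads of opposite clip
    orientation taken from coordinate-sorted SAM/BAM alignments. Reads whose
    CIGAR carries a long soft clip at the 3' end anchor the 5' breakpoint;
    reads clipped at the 5' end anchor the 3' breakpoint; a polarized overlap
    of the two reads' common string ties both anchors to the same variant
    junction. When a junction falls inside a short repeat the breakpoints are
    refined against the reference and reported as the left-most equivalent
    pair together with the number of bases they can slide. Includes
    reference-based false-positive filters, duplicate-call collapsing, a
    read-depth-ratio validation statistic, a closed-form false-negative-rate
    model with a Monte-Carlo verifier, and a synthetic junction-read simulator
    that writes standard FASTA and SAM so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
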