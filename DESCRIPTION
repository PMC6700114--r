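Package: motifcassette
Title: Coupling Bacterial Methyltransferases to Their Recognition Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking bacterial DNA methyltransferases to the
    methylation motifs they recognise. Designs strain-specific synthetic
    motif cassettes from a methylome's motif list (IUPAC-degenerate motif
    parsing, expansion and classification; randomised arrangement with
    adjacency and junction guards; annotated GenBank/FASTA output), scans
    arbitrary sequences for motif sites on both strands, computes per-motif
    modification statistics (detection rate, mean modification QV) from
    base-modification calls, discovers recognition motifs de novo from the
    calls, and sorts pooled long reads from linearised plasmids into
    per-methyltransferase groups by cassette and gene alignment. A synthetic
    data module simulates plasmids, noisy long reads and modification calls
    so the whole pipeline can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
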