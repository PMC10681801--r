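Package: pteseq
Title: Discovery of PRC1 Tethering Elements from ChIP-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate PRC1 Tethering Elements (PTEs) from
    depth-normalized ChIP-seq coverage of Polycomb subunits. Implements
    summit-window scoring of enriched regions with replicate concordance,
    discrete peak refinement (loess smoothing, extrema detection,
    relative-amplitude filtering over a parameter grid, mutual
    nearest-neighbour replicate pairing), a CCND2-like screen for
    PRC1-high/PRC2-low loci, DNA sequence-feature statistics around peaks
    (di-nucleotide difference maps, oriented homopolymer tract profiles,
    CpG windows, motif-centrality profiles, coverage metaprofiles), and
    nearest-TSS target-gene assignment with transcription groups. Ships a
    synthetic-data generator that emulates the signal structure of
    Polycomb ChIP-seq so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
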