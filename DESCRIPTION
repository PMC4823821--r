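Package: rbpkit
Title: RNA-Binding Protein Motif Records, FM-Index Scanning and
    Structure-Based Motif Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for working with experimentally validated RNA-binding
    protein (RBP) motifs. Manages motif record tables with gene-name
    normalization, the three-clause distinct-entry rule and conjunctive
    querying; builds position probability matrices (PPMs) from SELEX winner
    sequences or IUPAC consensus strings and computes the per-motif quality
    score; scans FASTA/multi-FASTA nucleotide sequences for exact motif
    matches with a Burrows-Wheeler transform (FM-index) and scores hits
    against genomic-functional-context backgrounds (exon +/- 250 nt, intron,
    CDS) with log2 odds ratios; and extracts candidate binding-site motifs
    from protein-RNA complex coordinate files by distance-based contact
    detection (hydrogen bond 3.0 Angstrom, van der Waals 3.9 Angstrom,
    runs of four or more contiguous contacted nucleotides). Deterministic
    synthetic-data generators make every component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
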