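Package: cbepipe
Title: Quantification and Genome-Wide Specificity Analysis for Zinc-Finger
    Cytosine Base Editors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for zinc-finger cytosine base editor (ZF-CBE)
    experiments. Quantifies C-to-T base editing, premature stop-codon
    conversion and indels from amplicon sequencing reads using an editing
    window derived from the zinc-finger binding arms; discovers genome-wide
    off-target candidate sites from USER-nicked whole-genome sequencing by
    piling up 5' read-start positions and applying read-count and
    read-fraction thresholds with control subtraction and repeat masking;
    quantifies off-target editing across multiplexed amplicon panels with
    prefix demultiplexing, replicate retention filters, germline
    allele-frequency masking and a maximum A/T frequency-change statistic;
    and scans coding sequences for codons convertible to stop codons by a
    single C-to-T event, classifying the 5' deaminase sequence context of
    each target cytosine. A synthetic-data module generates truth-known
    reads, alignments and panels so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
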