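Package: dsscan
Title: Detection of Discrete Selective Sweeps by Permutation-Normalized
    F_ST and Nucleotide-Diversity Genome Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-scan pipeline for detecting footprints of (artificial)
    selection between two diploid population groups. Parses multi-sample VCFs
    into per-site, per-group allele-frequency summaries, applies standard
    hard filters on caller INFO metrics, computes sliding-window weighted
    Weir-Cockerham F_ST and windowed nucleotide diversity differences
    (|delta-pi|), normalizes both against a permutation null obtained by
    shuffling per-site records across fixed genomic positions, thresholds the
    resulting Z-scores and merges significant windows into discrete selective
    sweeps (DSSs). Includes a Balding-Nichols synthetic-data generator with
    planted sweeps for end-to-end validation, SNP functional categorization
    with coding-effect calls, QTL/gene interval overlap, group-specific SNP
    extraction, minor-allele-frequency spectra and composite-LD decay
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
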