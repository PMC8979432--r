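Package: proxloop
Title: Protein-Directed Chromatin Interaction Calling from Proximity-Ligation Valid Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of low-input, tagmentation-assisted
    proximity-ligation (Hi-C-class) experiments that capture protein-directed
    chromatin interactions. Reads HiC-Pro style valid-pairs files and ChIP/CUT&RUN
    peak files; deduplicates, filters and classifies read pairs; calls long-range
    peak-anchored interactions by distance thresholding; benchmarks interaction
    sets against published loop calls (both-anchor matching) and computes
    replicate reproducibility via binned-coverage Spearman correlation; performs
    aggregate peak analysis (APA) on Knight-Ruiz balanced contact matrices;
    links interactions to GWAS SNPs and RefSeq-style gene promoters; and prepares
    non-promoter anchor sets for motif discovery. A synthetic-data generator with
    planted peaks, loops, distance-decay background and replicate draws provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
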