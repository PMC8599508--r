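Package: egtscan
Title: Gene-Tree Sorting for Endosymbiotic and Horizontal Gene Transfer
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects putative endosymbiotic gene transfers (EGT) from
    cyanobacteria and horizontal gene transfers (HGT) from other bacteria
    by sorting unrooted gene trees: eukaryote clades containing sequences
    from a focal taxon that branch sister to pure cyanobacterial (EGT) or
    other-bacterial (HGT) clades are counted per gene family and
    summarised as an EGT:HGT ratio. Includes phylogenomic supermatrix
    utilities (OTU merging, gene filtering, concatenation, fast-evolving
    site removal, chi-squared compositional site trimming, an elongation
    factor 2 residue-signature extractor), single-cell assembly QC rules
    (contig contamination flagging, ribotype clustering, marker
    completeness), and a seed-deterministic simulator that plants transfer
    events in gene trees with a truth table so every stage is verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
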