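Package: PULscope
Title: Detection and Comparative Analysis of Polysaccharide Utilization Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for calling polysaccharide utilization loci (PULs) in
    annotated Bacteroidetes genomes from tandem susCD-like gene pairs and
    degradative CAZyme content (seven-gene sliding-window rule), assigning
    PULs to glycan substrates from their GH/PL family content, normalizing
    gene-catalog read counts (CPM, RPKM) with diversity and rank-sum
    statistics, and screening gene clusters for horizontal-acquisition
    signals: GC-content anomalies in non-overlapping windows, elevated
    cross-genome protein identity relative to a reciprocal-best-hit
    background, and flank-conserved deletion events in related genomes.
    Includes a seeded synthetic-genome generator so every stage of the
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vegan,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
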