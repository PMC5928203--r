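Package: regulonscan
Title: Comparative-Genomics Reconstruction of Bacterial Transcription-Factor Regulons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs transcription-factor regulons across clades of
    annotated bacterial genomes. Discovers palindromic DNA binding motifs in
    upstream regions, builds symmetrized position weight matrices, scans
    genomes for strong and weak binding sites, propagates candidate regulon
    members across ortholog groups with consistency-check and phylogenetic
    footprinting filters, classifies repression versus activation from site
    position relative to -10/-35 promoter elements, and assigns
    arabinose/arabino-oligosaccharide utilization phenotypes from gene
    content. A seeded synthetic clade generator provides ground-truthed
    genomes so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
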