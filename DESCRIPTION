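Package: beediv
Title: Genomic Diversity Analysis of the Honey Bee Gut Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing shotgun-metagenomic diversity of simple
    host-associated bacterial communities such as the honey bee gut
    microbiota, at three taxonomic levels. Delineates sequence-discrete
    populations (SDPs) within phylotypes by average-nucleotide-identity
    clustering of single-copy core genes and validates them against
    metagenome-assembled ORFs (gap-zone analysis); quantifies phylotype and
    SDP abundance from positional core-gene coverage profiles by segmented
    linear regression, reporting terminus coverage and peak-to-trough
    replication ratios (PTR); profiles strain-level diversity through a
    single-nucleotide-variant filter cascade, polymorphic-site fractions,
    cumulative diversity curves and shared-SNV Jaccard distances; infers
    variably-associated gene families (the variome) and genomic islands from
    normalized gene-family coverage; and provides community-level statistics
    (greedy identity clustering, beta-dispersion, PERMANOVA). A synthetic
    data generator with planted ground truth makes every pipeline stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
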