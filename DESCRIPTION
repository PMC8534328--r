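Package: GEclust
Title: Graph-Entropy Seed-Growth Clustering of Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects overlapping functional modules in protein-protein
    interaction (PPI) networks by graph-entropy (GE) minimization. Implements
    the unweighted seed-growth GE algorithm together with two weighted node
    entropy variants (multiplied weights, GE-MW, and weighted ratios, GE-WR),
    edge weighting schemes for STRING-style confidence scores and Jaccard
    topological overlap, a cluster evaluation framework (average F-score,
    average precision, functional homogeneity, overlap statistics, and
    novel-member proposal against reference module sets), and seeded
    synthetic network generators (clique unions, planted partitions with
    overlapping blocks, Erdos-Renyi nulls) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
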