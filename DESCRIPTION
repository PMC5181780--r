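Package: edmine
Title: Strain Prioritization and Genome Mining for Enediyne Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico re-implementation of a high-throughput strain
    prioritization and genome mining workflow for enediyne natural products.
    Provides in-silico PCR screening of genome collections for the conserved
    five-gene enediyne polyketide synthase cassette (E3/E4/E5/E/E10),
    identity-cutoff dereplication of screening hits into clades via the
    translated 1-kb internal fragment of the E gene, construction of a genome
    neighborhood network (GNN) over gene-cluster proteomes with
    Karlin-Altschul E-value weighted edges, and rule-based prediction of
    enediyne ring size (9- versus 10-membered, from the exclusive presence of
    E2 or R3 marker genes) and peripheral moieties. A seeded synthetic-cohort
    generator produces ground-truthed mock genome collections so that every
    stage of the pipeline can be exercised and validated without external
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    phangorn
Config/testthat/edition: 3
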