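Package: thermavir
Title: Virome Mining of Hot-Spring Metagenomes: CRISPR Arrays, Contig
    Binning, and Phage Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for mining viral signal from
    thermal-spring metagenome assemblies. Detects CRISPR repeat-spacer
    arrays with two independent detectors and retains the consistent
    loci, computes repeat consensus sequences, clusters arrays into
    unique repeat types and matches them against a motif-consensus
    database; bins contigs by tetranucleotide frequency, coverage and
    G+C content and scores bin completeness against marker-gene lists;
    classifies contigs from ranked homology-hit tables by a
    phylum-unanimity / rank-majority voting rule and a best-hit screen
    with a query-coverage cutoff; and compares reconstructed phage
    genomes via dot plots, pairwise identity, tetranucleotide
    correlation networks, reciprocal-smallest-distance orthologs,
    shared gene cores, Welch tests on functional-category profiles and
    a proteome-distance tree. Ships a synthetic-community generator
    with a full ground-truth manifest so every stage can be exercised
    against planted features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    ape,
    cluster,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
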