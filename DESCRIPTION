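Package: phylokit
Title: Atomic, Chainable Operations for Phylogenetic Trees and Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit of small, composable operations for phylogenetic
    workflows. Reads and writes trees (Newick, Nexus, gzip-compressed) and
    multiple sequence alignments (FASTA, Phylip, Clustal, Nexus); cleans,
    renames, masks, extracts, concatenates, translates and back-translates
    alignments and builds bootstrap replicates; estimates evolutionary
    distances with closed-form nucleotide estimators (JC, K2P, F81, F84,
    TN93) and maximum-likelihood protein distances under empirical
    substitution models (Dayhoff, JTT, mtREV, LG, WAG); edits trees (prune,
    reroot, collapse, resolve polytomies, random generation), computes
    summary statistics (cherries, Colless and Sackin imbalance, patristic
    distances), compares topologies via bipartitions, and annotates branch
    supports with Felsenstein bootstrap proportions and the transfer
    bootstrap expectation. Ships two shell entry points designed for Unix
    pipelines, plus deterministic simulators for test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
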