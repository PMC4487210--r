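Package: fossilgraft
Title: Fossil Placement, Split Networks, and Root-Conflict Scans for
    Mixed Morphological-Molecular Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating fossil taxa into molecular phylogenies
    of small clades, built around the royal-fern (Osmundaceae) workflow:
    mean-character distance matrices from multistate morphological
    matrices with polymorphism and missing data, neighbour-net circular
    split systems with non-negative least-squares split weights and
    bootstrap/posterior bipartition support overlays, generalized Fitch
    parsimony with exhaustive fossil-insertion scans, Felsenstein pruning
    likelihoods under Mk, frequency-augmented multistate, and GTR+Gamma
    models, evolutionary-placement-style attachment of query taxa under
    parsimony- and likelihood-calibrated character weights, and
    partition-wise outgroup root-placement scans with gene jackknifing to
    expose conflicting rooting signal. Includes seed-deterministic
    synthetic-data generators emulating the study conditions, readers and
    writers for NEXUS character matrices, relaxed PHYLIP, FASTA, RAxML
    partition files, newick trees and splits-NEXUS, and a small command
    line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
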