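Package: seqevolve
Title: Fixed-Backbone Protein Sequence Design by Simulated Annealing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evolves protein-like amino-acid sequences to stabilize a fixed
    backbone under a composite statistical pseudo-energy. The score combines a
    Cbeta-neighbour burial potential, secondary-structure preferences, a
    distance-scaled finite ideal-gas (DFIRE-style) contact potential evaluated
    on Calpha atoms and side-chain centroids, a structure-based sequence
    profile over a reduced seven-class residue alphabet, and an anti-clustering
    restraint that suppresses artificial runs of same-class residues.
    Optimization uses simulated annealing with a geometric cooling schedule,
    Metropolis acceptance and a fully reproducible Mersenne Twister random
    stream. Includes a TM-score structural aligner for building profiles from
    structural analogs, derivation of all statistical tables from a reference
    set of structures, synthetic structure generators for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
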