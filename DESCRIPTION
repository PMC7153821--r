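Package: loopmsm
Title: Markov-State Modelling of Antibody CDR Loop Torsion Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic characterization of antibody complementarity-determining
    region (CDR) loop ensembles from backbone torsion trajectories: periodic
    sin/cos featurization of phi/psi angles, time-lagged independent component
    analysis (tICA) of the slow conformational subspace, k-means microstate
    discretization, reversible Markov-state model estimation with implied
    timescales and Chapman-Kolmogorov validation, PCCA+ coarse-graining into
    metastable macrostates with mean first passage times, free-energy surfaces
    in tIC space, and kinetic grouping of canonical-cluster median reference
    conformations. Includes a von Mises hidden-Markov torsion simulator with
    known ground-truth kinetics, average-linkage seed selection with medoid
    representatives, and phi/psi extraction from PDB coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
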