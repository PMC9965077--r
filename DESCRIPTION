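Package: fgcohesion
Title: Conformational Ensemble Compaction and Cohesion Analysis for
    FG-Repeat Nucleoporin Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to compare conformational ensembles of intrinsically
    disordered FG-repeat domains, such as the N-terminal FG domain of the
    nucleoporin NUP98, between a wild-type sequence and a point variant.
    Includes a coarse-grained (bead-per-residue) Metropolis Monte Carlo
    generator of replica ensembles with a tunable phenylalanine-phenylalanine
    cohesion interaction, multi-model PDB trajectory input/output, Kabsch
    superposition and RMSD-based replica stability classification,
    single-linkage clustering for representative conformations, a convex-hull
    hydrodynamic radius estimator with a Perrin-type shape correction,
    phenylalanine pair distance matrices with percent-variation screening and
    network-graph export, Shrake-Rupley solvent-accessible surface area with
    exposed/buried classification, and geometric hydrogen-bond detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
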