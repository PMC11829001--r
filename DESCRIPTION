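Package: protern
Title: Candidate Generation, Filtering and Ranking for PROTAC Ternary Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rigid-body candidate pipeline for PROTAC-mediated ternary
    complexes. Given an E3-ligase+anchor structure and a POI+warhead
    structure plus a set of rigid docking poses, the package filters poses by
    the anchor-warhead mass-centre distance and by a prioritised sequence of
    structure scores (clash stability, solvent-accessible surface area,
    Lennard-Jones interaction energy, interaction z-score), aggregates
    SASA and interface-quality ranks, refines survivors on translational
    (+/-4.5 A, 1.5 A step) and rotational (+/-15 degree, 5 degree step)
    grids, clusters them by fraction of common contacts, filters clusters by
    the lowest-energy quartile, and ranks re-clustered candidates. A full
    DockQ evaluation layer (fnat, interface and ligand RMSD, quality
    classes) and a deterministic synthetic toy-complex generator make every
    stage testable without external structure downloads or docking binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
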