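Package: cofilactin
Title: Construction and Geometric Analysis of Actin-Cofilactin Boundary Filament Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse (C-alpha level) structural models of the two
    severing boundaries that a cluster of bound cofilin creates on an actin
    filament, and measures the per-subunit observables used to characterise
    them. Provides rigid-body (Kabsch) superposition, slow- and fast-boundary
    splicing of bare-actin and cofilactin filaments, longitudinal replication,
    computational cofilin ablation, per-subunit helical twist and
    subdomain-dihedral (flatness) estimators, cleft distances, C-alpha contact
    counting, RMSD series, and a sigmoid boundary-transition model fitter.
    A seeded synthetic-filament generator emulates the statistical structure
    of molecular-dynamics ensembles for testing and calibration. Filaments are
    read and written as standard (multi-model) PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
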