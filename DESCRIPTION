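Package: memflux
Title: Water Flux, Water Wires, Contact Occupancy and Aggregation Analyses
    for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analyses for membrane-pump and aggregation studies:
    detection of single-water permeation events through a protein volume and
    the translocation success rate, per-frame hydrogen-bond water-wire graphs
    with maximum and mean wire-length distributions, salt-bridge and
    hydrogen-bond occupancy between protein chains (including phosphoserine),
    and entity counting for multi-copy aggregation under periodic boundaries.
    Supporting structural observables include Kabsch superposition, RMSD
    series, RMSD-matrix hierarchical clustering with medoid extraction,
    radius of gyration and Shrake-Rupley solvent-accessible surface area.
    Seeded synthetic-trajectory generators with machine-readable ground truth
    make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
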