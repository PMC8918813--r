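Package: vesseldyn
Title: Endothelial Cell Morphodynamics and Haemodynamics of Remodelling
    Trunk Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of endothelial cell behaviour during
    remodelling of the zebrafish trunk vasculature, from 3D+t nuclei
    tracks: rigid alignment of trajectories to a canonical frame with the
    dorsal aorta on the x-axis, windowed dorsoventral velocity profiles
    per vessel class, detection of inter-vessel immigration and
    emigration events, mitosis and cell-number accounting, and vessel
    diameter profiles. Includes an idealized intersegmental-vessel
    network model that solves Poiseuille flow on a vessel graph for nodal
    pressures, edge flows and wall shear stress over developmental time;
    statistics for discrete count distributions (a Kolmogorov-Smirnov
    variant with exact and permutation p-values) and circular migration
    directionality (Watson's two-sample U2); scratch-wound migration
    metrics for endothelial monolayers; and a synthetic-data generator
    with a ground-truth event ledger so the whole pipeline is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
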