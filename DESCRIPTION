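Package: fabkit
Title: Conformational and Interface Analysis of Antibody Fab Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the conformation of antibody Fab and Fv fragments from
    single structures and trajectory snapshots stored as multi-model PDB files:
    the six-parameter VH-VL pairing orientation (one torsion, four tilts, one
    distance), the elbow angle between the variable and constant modules via
    pseudo-twofold axes, solvent-accessible and buried surface area by a
    deterministic Shrake-Rupley quadrature, and hydrogen-bond and salt-bridge
    networks with per-snapshot occupancy.  Ensemble analytics (RMSD, RMSF,
    principal component analysis) and two-sample Kolmogorov-Smirnov comparison
    with Bonferroni control support contrasts between antibody variants.  A
    deterministic rigid-body Fab generator with known ground-truth geometry
    stands in for molecular-dynamics output in tests, and a dataset layer
    builds non-redundant structure sets and interface residue-position
    frequency profiles under Chothia numbering with insertion codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
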