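Package: gramconf
Title: Gram-Matrix Representation of Molecular Conformation and Geometric
    Pretraining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for encoding molecular 3D conformations as Gram matrices of
    origin-centered atomic coordinates, an E(3)-invariant representation that
    is exactly interconvertible with distance matrices, bond lengths and bond
    angles, and from which coordinates are recovered by eigendecomposition
    (classical multidimensional scaling). Includes a Graphormer-style graph
    transformer encoder trained to predict the Gram matrix from 2D molecular
    graphs under four supervision variants (distance matrix, distance plus
    origin distances, Gram matrix, Gram matrix plus bond length and bond angle
    auxiliary heads), a two-stage pretrain-then-property-prediction pipeline
    with frozen embeddings, conformer quality metrics (aligned RMSD, ensemble
    coverage and matching), scaffold and random dataset splitting, and a
    synthetic fixture generator producing random point clouds and small
    idealized-geometry molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
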