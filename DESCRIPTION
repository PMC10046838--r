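Package: pinndesign
Title: Physics-Informed Surrogate Modelling and Sequence Design for Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Protein sequence design against a molecular-dynamics-derived
    objective. A residual graph network maps a one-hot sequence plus
    Frenet-frame backbone geometry, propagated through a soft-adjacency graph
    Laplacian, to per-residue binding energy and structural deviation; the
    network is trained on trajectory summaries (time-averaged per-residue
    energy decompositions and per-residue RMSD) and then used as a cheap
    surrogate inside a projected-gradient optimizer that designs low-energy,
    structurally stable sequences over the probability-simplex relaxation of
    the discrete sequence space. A seeded synthetic molecular-dynamics
    generator with known ground truth makes the whole loop testable without
    external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
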