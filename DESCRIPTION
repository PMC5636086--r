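Package: ngeni
Title: Normal Mode-Guided Elastic Network Interpolation for Protein
    Transition Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates coarse-grained conformational transition pathways
    between two end-point protein structures. Each interpolation step is
    expressed as an optimal linear combination of elastic-network normal
    modes of the current intermediate (NGENI), with the conventional
    elastic network interpolation (ENI) over all Cartesian degrees of
    freedom available as a baseline and cross-check. Includes Calpha PDB
    input/output, sparse anisotropic-network Hessian assembly and
    eigensolvers, pathway-quality metrics (inter-pathway RMSD,
    convergence against experimental resolution, mode weighting-constant
    profiles, pseudo-bond geometry), deterministic synthetic
    two-conformation fixtures, and command-line drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
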