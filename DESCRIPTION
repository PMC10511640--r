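Package: vertexcalc
Title: Discrete Calculus and Couple Stresses for Vertex-Model Epithelial Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates confluent planar epithelial monolayers with the vertex
    model (area-perimeter elasticity, overdamped relaxation, growth by random
    cell division with T1 neighbour exchanges) and equips the resulting
    polygonal cell complex with a full discrete calculus: signed incidence
    matrices, sixteen discrete gradient/divergence/curl operators on the primal
    cell network and its dual triangulation, four scalar Laplacians, and
    Helmholtz-Hodge decomposition of per-edge vector fields. From equilibrium
    vertex forces it reconstructs the Maxwell-Cremona force potential, cell and
    tricellular-junction stress tensors, effective pressures, discrete Airy and
    Mindlin stress potentials with their eigenmode spectra, and couple-stress
    measures at tricellular junctions, including an affine (pressure-difference)
    approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
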