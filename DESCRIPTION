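Package: vasculr
Title: Hybrid Cellular Potts and Continuum Simulation of In Vitro
    Capillary-Like Network Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates short-term in vitro vasculogenesis of endothelial
    cells on a deformable biogel. A lattice-based Cellular Potts model
    drives cell migration, elongation and haptotaxis; coupled continuum
    fields describe viscoelastic gel deformation with long-range fiber
    elasticity and dish friction, gel density transport, and the
    diffusion, binding and advection of soluble and substrate-bound VEGF.
    Includes the matching quantification layer: skeleton-based network
    topology metrics (junctions, segments, total cord length), cell shape
    indices, migration-modality classification from direction histograms
    via sequential uniformity and dip tests, dose-response regression
    fits, and deterministic fixture generators for testing every stage in
    isolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
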