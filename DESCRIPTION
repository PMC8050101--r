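Package: actring
Title: Brownian Dynamics and Image Quantification of Actin Ring
    Formation in Spherical Confinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained Brownian dynamics of polymerizing,
    cross-linking semiflexible actin filaments confined in a sphere,
    with optional short-range attraction to the confining boundary as a
    proxy for membrane anchoring. Includes the quantification pipeline
    used to score the resulting structures: bundle-graph construction,
    ring and ring-like topology classification, ring-formation
    probability sweeps, simulated maximum-intensity projections, and an
    image-analysis branch (vesicle sphere fitting, 3D skeletonization of
    fluorescence z-stacks, membrane-normalized segment curvature, and a
    membrane-proximity index). A synthetic confocal generator renders
    vesicle z-stacks with known ground truth so that every image stage
    is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tiff
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
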