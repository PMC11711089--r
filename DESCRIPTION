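Package: scutes
Title: Mechanics of Crocodilian Head-Scale Self-Organization
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification toolkit for compression-driven
    skin folding in crocodilian embryonic head skin. Provides synthetic
    generators for light-sheet-like volumes and layered tissue meshes with
    known ground truth; image-derived field estimators (3D Canny boundary
    extraction, FFT collagen-fiber orientation, Hessian-curvature cell
    detection and proliferation-density fields); a finite-strain
    neo-Hookean growth simulator with fiber anisotropy, self-contact and
    viscous relaxation on layered tetrahedral meshes; curvature-based
    fold-network extraction with graph metrics; Gaussian-process Bayesian
    optimization of mechanical parameters against target metrics; and a
    mechanical-parameter morphospace sweep with pattern classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    lhs,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
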