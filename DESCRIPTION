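Package: migr3d
Title: Motility, Microstructure and Stiffness Analysis for 3D Cell
    Migration in Fibrous Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying 3D cancer-cell migration in collagen
    gels and the microstructure of the gels themselves.  Per-track
    motility statistics (time-averaged mean squared displacement,
    anomalous-diffusion exponent fits, speed, turning angles, track
    displacement), pore- and cell-size estimation from binary volumes
    via the largest-inscribed-sphere (local thickness) transform, AFM
    force-curve analysis with a quadratic-pyramid Hertz contact model,
    and cohort-level statistics (percentile thresholds, pore-size-binned
    fractions with exact two-proportion tests, normality-gated group
    comparisons).  A synthetic-data module generates trajectories,
    fiber-network volumes and force curves with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
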