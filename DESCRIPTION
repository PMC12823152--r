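Package: sedgrid
Title: Custom-Grid Sedimentation Velocity Analysis with Density Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of sedimentation velocity experiments from the
    analytical ultracentrifuge for particles whose density may be above or
    below the solvent density, such as lipid nanoparticles. Provides a
    conservative finite-volume Lamm equation solver valid for both
    sedimenting and floating species, non-negative least squares fitting of
    scan data over combined two-dimensional grids of sedimentation
    coefficient and partial specific volume at fixed frictional ratio,
    time- and radially-invariant noise decomposition, meniscus refinement,
    Monte Carlo error analysis, a straight-line parametrically constrained
    spectrum analysis, and D2O density matching to derive partial specific
    volume, molar mass and hydrodynamic radius distributions. Includes a
    synthetic-data generator emulating lipid-nanoparticle mixtures and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
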