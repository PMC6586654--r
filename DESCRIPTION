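Package: ipetr
Title: Individual-Particle Electron Tomography Reconstruction and Antibody
    Flexibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-particle three-dimensional reconstruction from negative-stain
    electron tomography tilt series, with a full simulation test-bed for flexible
    antibody-like particles. Simulates multi-domain phantoms with known
    conformational geometry and their tilt series (contrast transfer function,
    translational jitter, noise), reconstructs single-particle maps by iterative
    back-projection refinement with automatic filter and mask schedules,
    compensates the missing wedge by constraint-set iteration, estimates
    resolution by Fourier shell correlation, docks rigid domain models into maps,
    and quantifies conformational flexibility through domain distance and angle
    statistics with Gaussian and polynomial histogram models.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    bio3d,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
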