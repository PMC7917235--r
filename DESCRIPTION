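Package: ucgtube
Title: Ultra-Coarse-Grained Microtubule Models from Cryo-EM Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ultra-coarse-grained (UCG) bead models of microtubules
    directly from 3D cryo-EM density maps using convolution-initialized,
    density-weighted K-means clustering (CK-CG), parameterizes them as
    heterogeneous anisotropic harmonic networks (MVP-ANM), and measures
    mechanical properties: Young's modulus by force-clamp simulation and
    length-dependent persistence length from thermal-fluctuation Langevin
    dynamics. Includes MRC/CCP4 map input/output, a parametric synthetic
    microtubule density generator, worm-like-chain fixtures, a LAMMPS data
    exporter, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    minpack.lm,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
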