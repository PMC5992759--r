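Package: alphamicro
Title: Alpha-Particle Microdosimetry from Measured Track Fields and Virtual Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for cellular microdosimetry of alpha radiation. Computes
    single-hit and compound-Poisson nucleus specific-energy distributions from
    lists of individual alpha-particle tracks (entry point, direction, energy)
    combined with voxelized three-dimensional cell geometries; calibrates the
    microdosimetric survival slope against experimentally measured survival
    curves; and runs a virtual multicellular-spheroid Monte Carlo that scores
    nucleus and cytoplasm doses for alpha-emitting radionuclide carriers placed
    in the nucleus, in the cytoplasm, or on the nuclear or cell membrane.
    Charged-particle transport uses continuous slowing down on an embedded
    stopping-power table for alpha particles in liquid water.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
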