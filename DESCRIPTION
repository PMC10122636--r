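Package: boneibr
Title: Inverse Bone (Re)modeling with Voxel Micro-FE and Homogenized FE Models
Version: 0.1.0
Authors@R:
    person("boneibr", "developers", email = "boneibr@example.org", role = c("aut", "cre"))
Description: Estimates the physiological loading of a bone from its microstructure by
    inverse bone (re)modeling (IBR): unit load cases applied to a finite element model are
    scaled by non-negative least squares so that the strain energy density field matches a
    homeostatic target stimulus. Includes a linear-elastic voxel hexahedral micro-FE solver,
    KUBC homogenization of trabecular cubes, calibration of a density-dependent continuum
    target stimulus for homogenized FE models, density- and fabric-based (Zysset-Curnier)
    material mapping with mean-intercept-length fabric estimation, synthetic microstructure
    generators, and force comparison metrics (off-axis angle, angle/magnitude scores,
    regression and Lin's concordance correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
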