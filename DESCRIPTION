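Package: epidose
Title: EPID-Based 3D Dose Reconstruction and Dosimetric Verification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pre-treatment dosimetric verification of external-beam
    radiotherapy plans using electronic portal imaging device (EPID) images.
    Portal images acquired in air are deconvolved into incident energy-fluence
    maps with a two-exponential scatter kernel, and 3D dose is reconstructed in
    voxelized electron-density grids with a collapsed-cone
    convolution/superposition (CCCS) engine built on cumulative-cumulative
    kernel (CCK) tables. Reconstructed and planned dose grids are compared via
    3D gamma analysis, dose-volume histograms and structure dose-difference
    metrics. Synthetic slab phantoms, square-field fluences and forward
    simulated portal images are provided so the full chain runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
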