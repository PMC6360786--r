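Package: maizetls
Title: Terrestrial Laser Scanning Phenotyping of Maize Under Drought Stress
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for extracting individual-plant phenotypes from
    terrestrial laser scanning (TLS) point clouds of gridded maize plots and
    relating them to drought tolerance. Covers point-cloud preprocessing
    (statistical outlier removal, progressive TIN ground filtering, ordinary
    kriging of a digital terrain model, height normalization, density
    resampling), grid-based single-plant segmentation, voxel-based canopy
    profiling (plant area density and plant area index), projected canopy
    cover, drought tolerance indices (YRR, DSI, DRI) with distance-based
    clustering of varieties into tolerance groups, growth-stage dynamics, and
    the associated accuracy statistics. Includes a synthetic maize-scene
    generator with exact ground truth so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    FNN,
    deldir,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
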