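Package: terrapatch
Title: Terrain Health and Contamination Mapping from Aerial Image Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the health and garbage contamination of urban
    green spaces from low-altitude aerial RGB imagery. Large geotagged images
    are tiled into fixed-size square patches, each patch is classified into one
    of eight terrain classes (healthy, dry, unhealthy and non-vegetated ground,
    each with a contaminated variant) by a small convolutional neural network
    trained within the package, and the per-patch classifications are assembled
    into colour-coded grid maps with ground-sampling-distance based area,
    biomass and contamination statistics. Includes a deterministic synthetic
    scene generator for end-to-end testing without field data, micro-averaged
    confusion-matrix metrics, manifest-based dataset management, and a
    command-line interface covering tiling, training, prediction, evaluation
    and map export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jpeg,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
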