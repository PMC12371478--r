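Package: spinbench
Title: Spin Tests for Surface Maps with Distortion Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the spin test, a spatial permutation procedure for
    assessing the significance of correlations between per-vertex maps on
    triangulated cortical surfaces, together with diagnostic machinery for
    quantifying how spherical projection distorts spatial autocorrelation.
    Provides a mesh-based Gaussian random-field simulator (randomization
    method under a Gaussian variogram), global and local Moran's I statistics
    with inverse-distance spatial weights, Haar-uniform rotation sampling and
    nearest-neighbour spin construction, a per-spin quality score based on
    distance-matrix correlation, quality-thresholded null ensembles, and a
    benchmarking harness that measures false-positive-rate inflation caused
    by projecting a folded surface to a sphere. Reads and writes FreeSurfer
    binary geometry, GIFTI surfaces and functional maps, and plain CSV maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
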