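Package: ringcal
Title: Metric-Scale Recovery and Trait Extraction for 3D Plant Point Clouds
    Using a Printed Ring Fiducial
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monocular photogrammetric reconstructions (structure-from-motion
    followed by multi-view stereo) recover plant geometry only up to an
    unknown similarity transform. ringcal recovers the metric scale and an
    upright world coordinate system after reconstruction, from a printed red
    ring of known diameter placed next to the plant: the ring is localized in
    the colored point cloud by HSV color segmentation and geometric cluster
    selection, its supporting plane is estimated by PCA, a circle is fitted
    by RANSAC followed by geometric least squares, and the known diameter
    yields the scale factor while a Rodrigues rotation uprights the cloud.
    The package then extracts canopy traits (height, width, vertical
    distribution, projected and surface areas, compactness, occupancy) from
    the metric cloud, reads and writes colored PLY point clouds, generates
    fully ground-truthed synthetic scenes for validation, and ships a
    command-line pipeline with a robustness sweep over noise, occlusion,
    inclination and clutter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
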