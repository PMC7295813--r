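Package: actotug
Title: Tug-of-War Model of Actomyosin Cluster Positioning in Cell-Sized Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models and quantifies the positioning of nucleus-like clusters in
    cell-sized droplets of cytoplasmic extract, where inward-travelling
    actomyosin contraction waves compete with stochastically percolating
    actomyosin bridges that pull the cluster to the droplet boundary.
    Implements the crosslinker-turnover percolation model with its Monte-Carlo
    counterpart, the empirical wave-kinematics parameterization, the closed-form
    edge-positioning probability with analytic and numeric transition diameters,
    an event-driven stochastic simulator of cluster motion, statistical fitting
    of edge-probability curves, image quantification (droplet and cluster
    segmentation, DC-ratio, kymograph wave statistics, filament-length
    morphometry), and synthetic-data generators with recorded ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
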