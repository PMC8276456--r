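Package: stormtad
Title: Spatial Statistics of Replication Foci Within Chromatin Domains from STORM Localizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of single-molecule localization microscopy (STORM)
    point clouds of chromatin domains (TADs) and the replication foci they contain:
    synthetic-data generation with ground truth, spot detection and elliptical-Gaussian
    fitting with astigmatism-based 3D lookup, fiducial-bead drift correction and channel
    registration, cluster segmentation by a two-radius DBSCAN variant and by
    Voronoi-density thresholding, and the downstream spatial statistics (barycenter
    distance with analytic random-placement nulls, radius of gyration, radial density
    distribution, subsampling robustness) with tiered significance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    deldir,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
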