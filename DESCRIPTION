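Package: bottomuse
Title: Dead-Reckoned Foraging Tracks and Benthic Bottom-Use Clustering for
    Diving Predators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs three-dimensional foraging paths of benthic-diving
    marine predators from tri-axial accelerometer and magnetometer data,
    time-depth records and GPS fixes (dead-reckoning with GPS
    georeferencing), segments dives into descent, bottom and ascent phases,
    computes per-dive benthic foraging-effort metrics (bottom time,
    time-at-depth index, bottom distance, depth-variability index, bottom
    speed, sinuosity, colony distance), and identifies core bottom-use modes
    by Hartigan-Wong k-means clustering with silhouette-based selection of
    the number of clusters and backwards stepwise predictor selection.
    Includes a seeded synthetic-trip simulator that emits raw sensor streams
    with known ground truth so every pipeline stage can be validated.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
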