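Package: aqnet
Title: Spatial Correlation Weighted Networks for Air Quality Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds spatial correlation weighted networks from multi-site air
    quality index (AQI) time series. Sites (cities or monitoring stations) are
    nodes; an edge joins two sites when the Pearson correlation of their daily
    AQI series reaches the mean off-diagonal correlation, and its weight is the
    correlation divided by the normalized geodesic distance, rescaled into
    (0, 1]. Provides whole-network topology statistics (density, efficiency,
    rank degree), an influential-node score combining local weighted degree
    with a shortest-path global term (W_LGI), panel ingestion with daily
    aggregation and gap imputation, a synthetic spatio-temporal AQI generator
    for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
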