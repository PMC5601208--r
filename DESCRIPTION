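Package: forageEE
Title: Exploration-Exploitation Analysis of Central-Place Foraging Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the exploration-exploitation trade-off of
    central-place foragers from GPS tracking data. Raw fixes are cleaned,
    split into colony-to-colony trips, speed-filtered and rediscretized to
    equidistant steps; first-passage-time profiles over a radius grid locate
    the spatial scale of area-restricted search; a penalized change-point
    (Lavielle) segmentation of the first-passage-time series delimits
    area-restricted-search zones; per-trip traits (time in patch, foraging
    effort, size of patch, number of patches) are assembled and summarized
    into a principal-component strategy score; mixed models estimate
    repeatability (with parametric bootstrap confidence intervals),
    personality and demographic drivers, and fitness associations. A
    correlated-random-walk track simulator with full ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
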