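Package: flockr
Title: Location-Based Analytics for Group Movement in Unbounded Environments
Version: 0.1.0
Authors@R:
    person("flockr", "Maintainers", email = "maintainers@flockr.dev", role = c("aut", "cre"))
Description: Converts raw multi-member GPS tracks into movement periods,
    transforms positions into a path-adapted coordinate system (PACS), and
    extracts a catalog of individual- and group-level movement features:
    velocity-based, spatiotemporal (stretch index, convex hull, hull-clipped
    Voronoi), density-based clustering, directional-correlation leadership,
    movement-regularity (entropy, vector-autoregressive predictability) and
    doctrine-compliance metrics.  Group-level features feed a leave-one-out
    regression harness with pluggable sparse feature selection and
    selection-stability assessment.  Includes a seeded march simulator with
    ground truth for every downstream feature.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    xml2,
    jsonlite,
    igraph,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
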