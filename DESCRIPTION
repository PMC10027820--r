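Package: scanpathnet
Title: Scanpath Networks from Reading Eye-Movement Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns word-level eye-tracking fixation reports from text reading
    into directed weighted scanpath networks and quantifies them with five
    graph metrics: density, Freeman degree centralization, directed weighted
    transitivity, global efficiency, and small-worldness against a
    size-matched random reference ensemble. Includes fixation cleaning,
    network averaging and masking for group visualization, reader-level
    statistics (combined comprehension ability score, correlations,
    skilled versus less-skilled group comparisons), and a synthetic-reader
    simulator with tunable skip, regression, and refixation rates so the
    whole pipeline can be exercised without recorded eye-movement data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
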