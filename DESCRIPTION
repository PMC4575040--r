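Package: grouplife
Title: Spatial Agent-Based Simulation of Sociocultural Group Lifecycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A spatially explicit agent-based model of the lifecycle of human
    sociocultural groups on a square lattice of habitable patches. Small-scale
    single-celled groups (SCGs) grow logistically towards patch carrying
    capacity, expand by budding into empty patches, and fight wars over
    occupied ones under a linear (Lanchester) victory law; clusters of
    near-capacity peaceful SCGs fuse into large-scale multicellular groups
    (MCGs). The package provides landscape generation with aggregated or
    random productivity layouts, a yearly scheduler, a replicate-ensemble
    experiment harness, census and group-size-distribution metrics, and a
    command-line interface with CSV outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
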