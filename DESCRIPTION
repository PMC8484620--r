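Package: fragtrack
Title: Forest Loss and Fragmentation Tracking in Binary Landscape Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying habitat loss and fragmentation in binary
    forest/non-forest raster time series. Classifies every forest pixel into
    fragmentation classes (patch, edge, perforated, and three core classes by
    core-tract size), computes a Patch-Analyst-style landscape metric suite
    (patch density and size, edge density, shape index, perimeter-area ratio,
    fractal dimension), detects pixel-level change between epochs, summarises
    change over square analysis grids and regions, estimates compound annual
    deforestation rates, and overlays conflict-event point locations on change
    maps. Includes a seedable neutral-landscape simulator (spectral synthesis
    with edge-biased clearing) so every analysis stage can be exercised without
    real data, and a configuration-driven pipeline with provenance manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
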