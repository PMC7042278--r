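Package: floodring
Title: Dendroecology of Flood-Pulse Forests: Cross-Dating, Chronologies,
    Climate Correlations and Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dendroecological analysis of seasonally flooded
    (flood-pulse) tropical forests. Reads and writes Tucson/RWL ring-width
    archives and long-form climate, river-gauge and inventory tables;
    cross-dates ring-width series with Gleichlaeufigkeit and
    Baillie-Pilcher t statistics; builds moving-average-indexed master
    chronologies with mean sensitivity; correlates chronologies with
    lagged monthly climate and ENSO indices; fits and inverts a sigmoidal
    age-diameter growth model; reconstructs population age structure with
    Sturges diameter classes; estimates per-plot flood duration from
    water marks and daily gauge records; and simulates complete synthetic
    studies with planted ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
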