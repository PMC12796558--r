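Package: krillscape
Title: Spatiotemporal Biomass Hotspots from Acoustically Derived Densities
Version: 0.1.0
Authors@R: person("krillscape", "developers", role = c("aut", "cre"),
    email = "krillscape@example.org")
Description: Tools for linking acoustically derived euphausiid and fish
    densities to spatial biomass hotspots and multispecies co-occurrence.
    Implements dual-frequency dB-difference classification and NASC echo
    integration, spatiotemporal Tweedie random-field species distribution
    models on a k-means knot mesh (Laplace-approximate marginal likelihood),
    Moran's-I-calibrated Getis-Ord Gi* hotspot detection, hotspot overlap and
    co-occurrence statistics, redundancy analysis, and a fully seeded
    synthetic-data generator so the whole pipeline is testable without survey
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mgcv,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
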