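Package: forestedge
Title: Forest Edge Surface-Temperature Analysis on Synthetic Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how forest surface temperature changes with distance
    from the forest edge, how the strength of that edge effect scales with
    scene-level macroclimate, and how edge and interior temperatures compare
    to the thermal optimum for ecosystem productivity. Provides a synthetic
    fragmented-landscape generator with known ground truth (sigmoid edge
    temperature profiles, elevation lapse, per scene-by-overpass offsets,
    cloud dropout), exact signed Euclidean distance-to-edge rasters,
    penalized-spline additive models of temperature against distance with
    elevation smooths and ridge-penalized scene effects, per-scene
    log-distance slopes with Hampel outlier filtering and inverse-variance
    weighted quadratic meta-regression, a productivity temperature-gap
    analysis, and a deterministic end-to-end pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    splines,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    ape,
    optparse,
    withr
Config/testthat/edition: 3
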