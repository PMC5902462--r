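Package: gutmorph
Title: Morphometry and Biomechanics of Tension-Driven Embryonic Gut Growth
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for studying stress-dependent volumetric growth
    of the embryonic midgut under longitudinal tension. Provides Voronoi medial-axis
    morphometry of tubular organ silhouettes (midline length, diameter profile,
    solid-of-revolution volume) with an independent Bezier axisymmetric
    reconstruction as cross-check; biomechanical derivations (buoyancy-corrected
    hanging-mass force, applied stress, instantaneous elastic strain, effective
    tissue viscosity, dry-mass and cell-number changes, proliferation densities);
    glass-fiber cantilever dry-mass calibration; kymograph-based peristalsis
    quantification (contraction-wave frequency and propagation speed); cohort
    summaries with exact and asymptotic two-tailed Mann-Whitney tests and
    stress-response trend fits; and synthetic-data generators with analytic ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
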