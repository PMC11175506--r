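Package: epibuckle
Title: Junctional Buckling Mechanics and Morphometrics for Epithelial Cell Nests
Version: 0.1.0
Authors@R: person("epibuckle", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the mechanics of growing adherens-junction networks in
    non-dividing epithelial cell nests: cell boundaries are spring chains with
    bending stiffness, growing on a shrinking template, restrained by a
    plastically yielding elastic (Winkler) foundation and kept from
    self-intersecting by transient compression-only penalty springs.
    Includes the morphometric statistics used to characterise the resulting
    shape transition (area, perimeter, circularity, junction straightness,
    drift-corrected vertex fluctuation RMS, morphospace tables), intensity
    quantifications (junctional enrichment ratio, double-Gaussian membrane
    thickness mapping), in-silico physics experiments (laser-ablation recoil,
    Euler critical-load scaling, foundation buckling-mode selection), and
    deterministic synthetic-data generators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    mgcv,
    jsonlite,
    optparse,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
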