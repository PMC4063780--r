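Package: ecoclimex
Title: Ecoclimatic Index Modelling of Climate Suitability for Miscanthus Grasses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An open, testable implementation of a CLIMEX-style ecoclimatic
    index (EI) engine for mechanistic bioclimatic envelope modelling, bundled
    with fitted parameter sets for the Asian grasses Miscanthus sacchariflorus
    and M. sinensis. Computes weekly growth and stress indices from monthly
    climate normals via a soil-moisture bucket model, classifies EI into
    suitability classes with analytic equal-area grid weighting, and provides
    the surrounding analysis machinery: one-at-a-time parameter-perturbation
    sensitivity analysis with per-class area accounting, baseline-versus-future
    range overlay statistics (expansion, contraction, overlap, index of
    agreement), occurrence-based validation, and a synthetic gridded climate
    generator for fully offline, reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
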