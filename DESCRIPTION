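Package: macpol
Title: Boolean Attractor Analysis of Macrophage Polarization Networks
Version: 0.1.0
Authors@R:
    person("Human Systems", "Modeling", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dynamical analysis of Boolean gene regulatory networks
    under the synchronous updating scheme, oriented at macrophage polarization
    in a tumor microenvironment. Parses BoolNet-style and JSON rule files,
    enumerates fixed-point and cyclic attractors with exact basins (exhaustive
    mode) or sampled estimates, annotates attractor states with M0/M1/M2a-d
    phenotype labels from a declarative marker scheme, builds cell-fate maps
    from persistent bit-flip (clamp) perturbations, and embeds binary attractor
    states in two dimensions with exact t-SNE. Includes generators for random
    N-K networks, analytic fixtures with known attractor structure, and a
    curated synthetic macrophage transcription-factor network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
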