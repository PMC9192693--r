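Package: recolor
Title: Homophily Testing in Node-Colored Networks via a Random-Recoloring Null Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses and measures homophily and heterophily in networks whose
    nodes carry a categorical attribute (a "coloring"), using an endogenous
    null model: the observed coloring is compared against a uniformly random
    recoloring of the same graph with the same color profile. Provides exact
    first- and second-order moments and z-scores of intra- and inter-class
    edge counts and of per-class isolated-node counts, distribution-free
    significance via Chebyshev/Cantelli bounds with Bonferroni-style multiple
    testing control, a [0,1] global homophily index, exact-enumeration and
    Monte Carlo null oracles, planted-partition generators for validation,
    and readers for STRING-style protein interaction files and Pokec-style
    profile tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
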