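Package: tetraconv
Title: Tetrahedral Colour-Space Modelling and Phylogenetic Convergence Tests
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models reflectance spectra as colour loci in an avian
    tetrahedral colour space (four-receptor quantum catches with von Kries
    chromatic adaptation), quantifies morphospace occupancy with convex-hull
    volumes and overlaps, defines target regions with minimum-volume
    enclosing ellipsoids, and tests for convergent evolution by counting
    tree branches that evolve from outside a target region to inside it,
    with significance assessed against a Brownian-motion null distribution
    simulated on the phylogeny.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
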