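Package: phytoregion
Title: Quantitative Floristic Bioregionalization and Driver Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to delimit spatially cohesive floristic sub-regions from
    site-by-species incidence data and to rank candidate environmental
    drivers of the resulting regionalization. Implements pairwise Simpson
    (beta-sim) turnover, non-metric multidimensional scaling with Shepard
    diagnostics, principal coordinates with Cailliez correction,
    inverse-distance interpolation of compositional axes onto a regular
    grid, L-method knee detection with modal consensus over the maximum
    cluster number, K-means regionalization, Moran eigenvector maps and
    correlograms, derived climate predictors (Koeppen aridity index,
    glacial-interglacial envelope distances), multinomial logistic driver
    models ranked by AICc with deviance partitioning, and two-way
    PERMANOVA comparison of classification schemes. A seeded synthetic
    landscape generator with planted sub-regions and known drivers
    supports end-to-end recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    vegan,
    ape,
    nnet,
    geosphere,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
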