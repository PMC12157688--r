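Package: epp
Title: Automated Cytometry Phenotyping by Exhaustive Projection Pursuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic, recursive two-dimensional gating of flow and mass
    cytometry event data. Dimensions are qualified by Kullback-Leibler
    divergence from normal (and exponential) references, every qualified
    dimension pair is examined with a fast 257x257 kernel density estimate,
    modal clustering delineates candidate populations, a density-based
    merging test removes boundaries whose density dip is not statistically
    significant, and a dual-graph enumeration finds every continuous
    two-part separation boundary. The best-scoring split is applied
    recursively until no statistically supported split remains, yielding a
    conventional gating tree whose leaves are algorithmic phenotypes.
    Includes logicle display transforms, FCS and CSV input, JSON gating-tree
    and per-event assignment output, population similarity coefficients, and
    a synthetic mixture generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
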