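Package: netfreq
Title: Network-Based, Binless Frequency Analysis of Univariate Data
Version: 0.1.0
Authors@R:
    person("CSUN", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Binless frequency analysis of one-dimensional numeric data via a
    similarity network: every pair of values within a half-width zeta of each
    other is linked, node degree plays the role of a histogram bar height, and
    the value of maximum degree estimates the mode. The half-width is selected
    automatically by scanning a grid of zeta values and detecting when the
    proportion of nodes in the giant (largest) cluster stabilises. The package
    also reports a homogeneity index (zeta over the mode), network measures of
    spread (diameter and average shortest-path length), density-based outliers
    (values outside the giant cluster), seeded subsampling for large inputs, a
    simulation study over a catalog of parametric distributions, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
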