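Package: microclonality
Title: Spatial Clonality Analysis of Multicolor Fate-Mapped Microglia Around Amyloid Plaques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies clonal expansion of multicolor (Confetti) fate-mapped
    microglia around amyloid plaques from tables of segmented cell and plaque
    centroids. Implements plaque-proximity classification of microglia into
    plaque-associated (PAM) and non-plaque-associated (non-PAM) states, a
    Monte Carlo ring-density clonality test that compares same-color annulus
    densities against a label-position-shuffling null with empirical
    confidence envelopes, Voronoi-tessellation clone calling with clone
    territory and clone-to-plaque contact statistics, and stratified
    clone-size versus plaque-volume regressions. A synthetic-tissue generator
    reproduces the statistical structure of the imaging data (plaque-seeded
    clonal clusters, sparse stochastic four-color labeling, and the image /
    replicate / group hierarchy) so that every analysis stage is testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
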