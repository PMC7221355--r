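Package: betticonn
Title: Betti-0 Curve Analysis of Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Topological data analysis of subject-level functional
    connectomes via the zeroth Betti number of the Rips filtration on the
    1 - r correlation distance. Computes Betti-0 curves and their scalar
    summaries (area under the curve, slope, kurtosis of the merge-value
    distribution), weighted rewiring null models with empirical p-values,
    logistic-regression group inference at whole-brain and subnetwork
    levels with cluster-based permutation family-wise error correction,
    edge-wise proportion contrasts at fixed filtration values, Kendall's
    coefficient of concordance across parcellations, and a synthetic
    two-group cohort generator for community-structured correlation
    matrices with implanted group effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
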