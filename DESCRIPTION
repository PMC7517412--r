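Package: fdnet
Title: Fractal-Dimension Structural Covariance Networks of the Cerebral Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the three-dimensional box-counting fractal dimension of
    labelled cortical parcellations, builds group-level structural covariance
    networks from regional fractal dimension values, decomposes them into
    modules by weighted modularity maximisation, summarises intra- and
    inter-lobe connectivity, and compares two cohorts with regional Welch
    t-tests, Benjamini-Hochberg false-discovery-rate control, and a
    sex-balanced permutation scheme for network properties. Ships a rearranged
    68-region Desikan-Killiany atlas, generators for fractal phantoms with
    known analytic dimension, and a synthetic two-group cohort simulator with
    planted covariance modules and regional group effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
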