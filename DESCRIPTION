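Package: bayesconn
Title: Bayesian Reconstruction of Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs functional complex networks from multivariate time
    series under both frequentist and Bayesian inference. Provides the exact
    and approximate posterior density of the Pearson correlation coefficient
    under the bivariate-normal model with noninformative nuisance priors,
    ensemble network sampling with density thresholding, seven binary-graph
    topology metrics (efficiency, degree-distribution entropy, clustering,
    assortativity, Louvain modularity, small-worldness, information content),
    a bias statistic quantifying how point-estimate networks overestimate
    topological structure, and a cheap Fisher-transform rewiring correction
    using effective degrees of freedom for autocorrelated series. Includes
    synthetic generators (star-coupled noise map and a BOLD-like fMRI
    emulator) and readers for delimited time-series matrices and the UCI EEG
    trial format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
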