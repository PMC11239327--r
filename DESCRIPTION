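Package: hmmbiclust
Title: Bayesian Biclustering with a Hidden Markov Prior on Ordered Features
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Model-based biclustering of expression matrices in which every
    sample cluster classifies each feature as overexpressed, underexpressed or
    irrelevant, with a first-order hidden Markov prior along a biologically
    ordered feature axis encouraging neighbouring features to share states.
    Fitting is by Gibbs sampling with conjugate full conditionals (truncated
    normal hierarchical means, inverse-gamma variances, Dirichlet mixture and
    transition probabilities); the number of sample clusters is chosen by a
    deviance information criterion scan, and recovered biclusters are scored
    against a reference with a symmetrized F1 similarity. Includes the
    simulation-study generators with known ground-truth biclusters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
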