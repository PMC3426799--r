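Package: bnbag
Title: Bootstrap Model Averaging for Bayesian Network Structure Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns the structure of discrete Bayesian networks from limited
    data by bootstrap model averaging (bagging). Provides decomposable
    Bayesian-Dirichlet (K2/UPSM, DPSM, BDe) and penalized-likelihood
    (BIC, MDL) scoring metrics over weighted sufficient statistics, greedy
    hill-climbing search with randomized restarts inside the
    sparse-candidate framework, ordinary and Bayesian bootstrap resampling,
    single-best and double-averaging aggregation of edge features, an
    analytic bound on the number of resamples needed for stable edge
    probabilities, permutation-based selection of the edge-inclusion
    threshold, and false-positive/false-negative evaluation against a
    reference network. Includes a BIF (Bayesian Interchange Format)
    reader/writer, forward sampling, and generators for synthetic benchmark
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
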