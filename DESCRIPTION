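Package: netpred
Title: Structure Predictability of Complex Networks via Lossless Compression
Version: 0.1.0
Authors@R:
    person("Network", "Methods Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the intrinsic link-prediction limit of an undirected
    network from its structure alone.  Implements a two-stage label-free
    lossless graph compressor (partition-refinement encoding followed by an
    adaptive arithmetic coder) yielding a normalized compression length L*,
    the leave-one-out rank-distribution entropy H* of link-prediction
    algorithms (with the best-performing-algorithm minimum, BPAA), the
    analytic linear law connecting L* and H* for edge-independent random
    graphs, and entropy-constrained upper and lower bounds on achievable
    link-prediction precision, including a dataset-value estimate.  Ships
    seeded generators for Erdos-Renyi, Chung-Lu and ring-lattice networks
    plus shuffle/add/remove perturbations for property-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
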