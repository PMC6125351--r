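Package: dyntopo
Title: Dynamic Positive and Negative Functional Connectivity Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis for
    multivariate BOLD-like time series, with weighted stepwise functional
    connectivity (SFC) and optimal step-distance assignment over positive
    connections, node-level Euclidean topology-transition series for the
    positive and negative networks, and Granger causality between the two
    transition dynamics. Includes seeded generators of synthetic signals
    with known ground truth (phase-lag chains that produce negative
    correlations from propagation delay along positively coupled modules,
    and piecewise-stationary 'follower' signals in which negative-network
    reconfigurations track positive-network reconfigurations at a known
    lag), plus a pipeline driver with TSV/JSON/YAML input-output and
    optional NIfTI volume extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    RNifti,
    optparse
Config/testthat/edition: 3
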