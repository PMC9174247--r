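Package: echonet
Title: Contagion Dynamics and Echo-Chamber Biases on Homophilic
    Scale-Free Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for information spreading on attributed
    scale-free networks. Generates Barabasi-Albert-type networks with a
    binary minority/majority attribute and tunable homophily, runs Simple
    (one-shot SIR), Complex (threshold) and Hybrid contagion to their
    absorbing states, estimates the four group-to-group information
    transmission probabilities by Monte Carlo, decomposes them into mean
    transmission, emissivity, receptivity and echo-chamber biases, and
    locates critical cascade thresholds from final-density histograms,
    including detection of threshold divergence. Also reads empirical
    attributed edge lists, extracts largest components, and estimates the
    homophily parameter by simulation matching.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
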