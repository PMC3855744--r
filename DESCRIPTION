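Package: mitodyn
Title: Photoactivation-Based Quantification of Mitochondrial Network Dynamics in Skeletal Muscle
Version: 1.0.0
Authors@R: person("mitodyn", "maintainers", email = "mitodyn@example.org", role = c("aut", "cre"))
Description: Simulates a skeletal-muscle mitochondrial network undergoing
    stochastic fission and fusion with intra-network content mixing, renders
    confocal-like two-channel (photoactivated tracer + TMRE) time-lapse image
    series, quantifies tracer migration out of a photoactivation region in
    sarcomere-length migration steps (m-steps), fits the two-phase linear rate
    model (fast diffusion-limited spread in the first two minutes, slow
    fission/fusion-limited spread afterwards), and scores mitochondrial
    fragmentation, protein aggregates and aggregate-localized membrane-potential
    depolarization.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    igraph,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
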