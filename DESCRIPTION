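Package: mmbann
Title: Molecular-Marker-Based Attractor Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction, simulation and analysis of attractor neural
    networks whose connections are innate, set by a metric on model
    molecular markers distributed over neurons.  Supports isolated point
    attractors (d = 0) and ring/bump attractors (d = 1, including two-ring
    and asymmetric dynamic variants), asynchronous McCulloch-Pitts dynamics
    with threshold accommodation, leaky integrate-and-fire spiking dynamics
    with calcium-dependent adaptation, noise-robust perceptron readout,
    self-organizing-map learning on attractor states, and the associated
    analysis statistics (L-plots, distance curves, period and state-count
    estimation, plateau distance, critical marker load, dimension bounds).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
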