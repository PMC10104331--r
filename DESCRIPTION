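Package: spikecause
Title: Causal Effect Estimation in Spiking Networks via the Spiking Discontinuity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the causal effect of single spiking neurons on
    a reward signal using the spiking discontinuity estimator (SDE), a
    regression-discontinuity design applied at the spike threshold. Includes a
    leaky integrate-and-fire (LIF) network simulator with correlated input
    noise, piecewise-constant and piecewise-linear discontinuity estimators
    with an observed-dependence baseline, an online least-squares learning rule
    that uses the estimated effects for reward optimization, finite-difference
    theory checks relating single spikes to reward gradients, and scripted
    experiment drivers for bias/variance, network-width and network-depth
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
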