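Package: ewsassess
Title: Assessing Early Warning Signals of Critical Transitions in
    Spatially Structured Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for generating and analysing spatio-temporal data from
    stochastic lattice dynamical systems that undergo critical transitions,
    and for assessing how well generic early warning signals anticipate
    those transitions.  Fast-slow lattice models with diffusive coupling and
    additive white noise are integrated with the Euler-Maruyama scheme;
    temporal indicators (rolling variance, skewness, lag-1 autocorrelation
    and autoregression of the spatial mean) and spatially informed
    indicators (spatial variance, spatial skewness, Moran's I, and the
    leading eigenvalue of the snapshot covariance matrix) are computed on
    detrended data; indicator trends are quantified with Kendall's tau and
    tested with the Hamed-Rao modified Mann-Kendall test; and indicator
    performance is summarised over rolling-window grids and replicate
    ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
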