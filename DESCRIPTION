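Package: thfates
Title: Sigmoidal-Network Simulation of TH17/iTreg Reciprocal Differentiation
Version: 0.1.0
Authors@R:
    person("Robin", "Devlin", email = "rdevlin@example.org",
           role = c("aut", "cre"))
Description: A simulator for coupled T-helper-17 / induced-regulatory-T-cell
    lineage commitment built on a generic sigmoidal ordinary-differential-
    equation formalism for small gene-regulatory networks. Ships three
    registered networks for the RORgammat/Foxp3 mutual-antagonism circuit
    (a perfectly symmetric two-gene switch, a variant with TGF-beta signal
    intermediates, and an asymmetric six-species network with IL-6/STAT3 and
    retinoic-acid inputs), together with steady-state enumeration, phase-plane
    analysis (nullclines, basins of attraction), one-parameter bifurcation
    continuation with pitchfork/saddle-node detection, and a heterogeneous-
    population layer that samples cell-to-cell parameter variability and
    simulates induced differentiation, polarization, and cytokine-driven
    reprogramming protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
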