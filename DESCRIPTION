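Package: rloopwalk
Title: Random-Walk Kinetics of CRISPR-Cas Cascade R-Loop Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of R-loop formation by the type I CRISPR-Cas
    Cascade surveillance complex as a biased one-dimensional random walk over
    the crRNA-DNA hybrid. Builds per-base-pair free-energy landscapes for
    arbitrary mismatched targets, derives detailed-balance birth-death rate
    chains under applied DNA torque, and solves first-passage problems for
    formation times, coarse-grained state rates and occupancies. Includes
    kinetic Monte-Carlo and Brownian-dynamics simulators of the
    magnetic-tweezers readout, hidden-Markov trajectory analysis with dwell-time
    rate extraction, triple-exponential analysis of bulk fluorescence kinetics,
    global parameter fitting with profile confidence intervals, and off-target
    prediction surfaces (mismatch position scans, supercoiling-dependent seed
    lengths, double-mismatch proximity matrices, in vivo torque estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
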