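Package: dualRTK
Title: Dual IGF1R/InsR Signaling Network Modeling and Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action ordinary differential equation model of signaling
    through the insulin-like growth factor 1 receptor (IGF1R) and the insulin
    receptor (InsR), with shared downstream MAPK and PI3K/Akt/mTORC1/RPS6K
    cascades and IRS-centered negative feedback loops. Provides a reaction-table
    network compiler, stiff ODE simulation under stimulation, dose-ladder and
    inhibitor conditions, parallel-tempering Markov chain Monte Carlo parameter
    estimation against RPPA-style phospho-protein time courses with profiled
    per-observable scales, Latin hypercube virtual-cell ensembles with
    percentile trajectory bands, systematic single-parameter perturbation
    scanning with log2 fold-change readouts, two-fold local sensitivity
    analysis, and a synthetic RPPA data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    lhs,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
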