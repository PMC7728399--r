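Package: pfaffr
Title: Input/Output Mapping of Gene Circuits from Transient Transfection
    Flow Cytometry
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates transient-transfection flow-cytometry data for
    constitutive gene mixes and three-node synthetic gene circuits
    (fan-out, reinforced incoherent feed-forward, incoherent and coherent
    feed-forward loops, feedback motifs), and implements the PFAFF
    peak-finder workflow that extracts stable-integration-equivalent
    input/output mappings, including bimodal ones, from such data.
    Includes the copy-number analytics that justify the approach
    (anticipated versus empirical copy-number modes, conditional noise,
    bimodality divergence metrics) and a validation harness that
    correlates modes extracted from transient data against matched
    stable-integration simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    deSolve,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: FlowCytometry, Software, SystemsBiology, Network
RoxygenNote: 7.3.3
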