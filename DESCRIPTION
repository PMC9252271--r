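Package: antennalobe
Title: Composable Feedback-Circuit Models of the Drosophila Antennal Lobe
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the feedback logic of the Drosophila antennal
    lobe. Extracts local-neuron port connectivity patterns and feedback-loop
    classes from synaptome tables, models the odorant space as receptor
    binding/dissociation rate tensors with concentration waveforms, composes
    executable glomerular circuits from feedback motifs (presynaptic OSN
    inhibition, PN-loop, LN-to-LN), and simulates them with a fixed-step
    conductance-based spiking network engine (odorant transduction,
    Connor-Stevens axon hillocks, alpha synapses) to characterize steady-state
    projection-neuron responses under concentration-modulated affinity sweeps.
    A synthetic-connectome generator with planted ground truth supports testing
    without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
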