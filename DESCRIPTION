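Package: spikerepair
Title: Lesioning and Neurostimulation Repair of a Spiking Sensorimotor
    Network via Kernel Adaptive Inverse Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop testbed coupling a recurrent spiking network of
    sensorimotor cortex (7 subpopulations, conductance-based
    integrate-and-fire units) to a planar two-joint virtual arm with
    Hill-type activation dynamics.  Simulated lesions (cell silencing,
    synapse removal) degrade a reach learned by reward-modulated STDP;
    the surviving circuit is probed with single- and multi-cell
    microstimulation, an inverse model of the motor layer is trained by
    quantized kernel least-mean-squares in a reproducing kernel Hilbert
    space on spike trains (Schoenberg kernel over smoothed intensity
    functions), and repair neurostimulation derived from the inverse
    model is evaluated with SPIKE-distance, SPIKE-synchronization,
    shifted-PETH correlation and behavioral distance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
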