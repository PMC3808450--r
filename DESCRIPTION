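Package: convallis
Title: Voltage-Dependent Unsupervised Synaptic Plasticity in Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clock-driven simulation of conductance-based integrate-and-fire
    neurons with a voltage-dependent "valley" plasticity rule that performs
    unsupervised learning by increasing the skewness of the subthreshold
    membrane-potential distribution under a homeostatic firing-rate
    constraint. Includes an efficient backward-in-time eligibility algorithm
    with a direct-path reference implementation, STDP-family baseline rules
    (all-to-all, nearest-neighbour, triplet), synthetic spatiotemporal
    stimulus generators (circular-Gaussian rate ensembles and
    cochleogram-like multi-class intensity patterns), builders and
    calibration for feedforward and recurrent network architectures,
    reproductions of classical in vitro plasticity protocols (spike pairing,
    tetanus, triplets, pairing-frequency sweeps), and analysis metrics with a
    linear spike-count readout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
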