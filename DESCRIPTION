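Package: rollkernel
Title: M-Sequence Reverse Correlation for Optic-Flow-Sensitive Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end reverse-correlation analysis of spiking responses to
    maximal-length shift-register (m-sequence) optic-flow stimuli, as used to
    characterise roll-sensitive descending neurons in flies. Provides m-sequence
    generation and verification, starfield stimulus geometry and per-frame
    stimulus composition, a linear-nonlinear Poisson generator of synthetic
    recordings that emulates the recording protocol, impulse-response (kernel)
    extraction by cross-correlation with Gaussian smoothing, kernel
    parameterisation (amplitude, time to peak, half-width, decay, return to
    baseline, spike rate), leave-one-neuron-out LN-model prediction validation
    with spike-shuffling controls, and nonparametric group statistics
    (Kruskal-Wallis, Mann-Whitney with Benjamini-Hochberg correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
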