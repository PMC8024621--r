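Package: kuramotoFC
Title: Frequency-Resolved Functional Connectivity from Delay-Coupled Phase Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the generalized (delay-coupled, noisy) Kuramoto model on
    weighted connectomes and derives frequency-resolved functional networks from
    the pairwise correlation index. Includes loaders and a synthetic generator
    for weight/distance connectome matrices, an adaptive Bogacki-Shampine delay
    differential equation integrator with Euler-Maruyama noise, correlation-index
    functional connectivity with ensemble averaging, weight- and distance-binned
    correlation summaries, structure-function similarity distances, an analytic
    two-oscillator phase-locking oracle, and reproducible experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
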