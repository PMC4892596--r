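Package: chemorace
Title: Run-and-Tumble Chemotaxis: Linear-Response Theory, Agent-Based
    Simulation and Gradient-Race Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how (im)precise adaptation of the Escherichia
    coli chemotaxis pathway affects gradient climbing. Implements the
    linear-response chemotactic-velocity theory for a bilobed impulse-response
    kernel (closed-form and quadrature chemotactic coefficients, optimal memory
    rate, motor-response amplitude for Hill and allosteric motor curves), a
    seeded three-dimensional agent-based run-and-tumble simulator with
    kernel-based sensing and concentration-dependent run times, a
    drift-diffusion continuum model of bacterial transport in microfluidic
    channels with source and absorbing boundaries, trajectory run/tumble
    segmentation and speed estimators, front-progression ("speed race")
    statistics, and a synthetic-data generator emulating homogeneous tracking
    assays and multi-replicate channel-race assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
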