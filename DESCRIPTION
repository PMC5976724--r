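Package: hbihsync
Title: Synchronization, Metastability and Multi-Stability in Small-World
    Networks of Chaotic and Non-Chaotic Conductance-Based Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Newman-Watts small-world networks of electrically
    coupled Huber-Braun thermoreceptor neurons extended with a
    hyperpolarization-activated current (HB + Ih), and analyses how chaotic
    versus non-chaotic single-neuron dynamics shape the transition to network
    synchrony. Provides the conductance-based single-neuron model with
    temperature scaling, fixed-step Euler integration of single neurons and
    coupled networks (compiled), maximal Lyapunov exponent estimation by the
    two-trajectory renormalization method, firing-rate and firing-pattern
    characterization with burst statistics, parameter-plane scanning and
    firing-rate-matched population sampling, instantaneous-phase extraction
    (low-pass filtering plus complex Morlet wavelet), Kuramoto order parameter
    and metastability, windowed functional connectivity and functional
    connectivity dynamics (FCD) with a variance-based multi-stability measure,
    surrogate phase/voltage fixtures with closed-form ground truth, and an
    orchestrated conductance-sweep pipeline with seed-controlled topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
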