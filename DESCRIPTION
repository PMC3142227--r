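Package: brnnoise
Title: Volume-Dependent Noise Analysis of Biochemical Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Exact Gillespie stochastic simulation of mass-action biochemical
    reaction networks initialized at their deterministic ODE steady state,
    with tools to characterize intrinsic molecular noise in both the time and
    frequency domain across a grid of cellular volumes. Provides a plain-text
    reaction-table model format, a reconstructed 66-species signal
    transduction network combining PKC, MAPK, PLA2 and PLC-beta modules,
    zero-order-hold sampling of event traces with a captured-power criterion
    for choosing the sampling frequency, anti-aliased decimation, one-sided
    periodogram power spectral density estimation with bin smoothing and
    ensemble averaging, log-log spectral slope estimation for power-law
    (1/f^alpha) noise, coefficient-of-variation and frequency-of-change
    statistics, and reference generators (white noise, random walk, 1/f^alpha,
    immigration-death, isomerization) with known analytic behavior.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, parallel, Rcpp, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
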