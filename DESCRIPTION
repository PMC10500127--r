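Package: shotnoise
Title: Generalized Shot-Noise Simulation and Spectral Analysis of Neural
    Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates local field potential (LFP) signals as generalized
    shot noise: renewal point-process event trains (gamma-interval, periodic,
    compound-mixture, and phase-modulated) are convolved with parametric
    single-event waveforms (alpha synaptic response, real Morlet wavelets,
    Hann pulses, RC impulse responses) and summed with RC-filtered background
    noise. Provides Welch power spectral density estimation with
    non-overlapping Hann-tapered segments, spectral peak detection, power-law
    slope fitting, the analytic (Bartlett) spectrum of gamma renewal
    processes, and matched-Poisson surrogate confidence bands for testing the
    significance of structure in event-timing spectra. Config-driven
    experiment runners regenerate a library of canonical simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
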