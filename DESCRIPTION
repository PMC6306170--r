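Package: lfpvc
Title: Volume Conduction and Differential Local Field Potential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how the local field potential (LFP) recording
    montage shapes spectral and functional-connectivity estimates. Implements
    the closed-form ohmic volume-conduction model of a point current source
    (potentials, electrode-pair differences in the exact, distal and local
    regimes, common-mode rejection ratio and signal-to-noise expressions for
    referential versus bipolar montages), a hypnogram-driven synthetic
    multi-area LFP generator rendered through that forward model, and the
    analysis pipeline used to compare the two montages: state-conditioned
    Welch spectra, magnitude-squared and imaginary coherence, 10-14 Hz burst
    detection, burst-triggered coherence, cross-correlation peak-lag
    distributions, and a coherence-versus-noise simulation with a hyperbolic
    secant fit. Sessions round-trip through European Data Format (EDF) files
    with plain-text hypnogram and ground-truth sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
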