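Package: wavesync
Title: Wavelet Analysis of Spatial Synchrony and Its Drivers in
    Ecological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying time- and timescale-resolved spatial
    synchrony in site-by-month ecological monitoring data and attributing
    it to environmental drivers. Implements the continuous Morlet wavelet
    transform with cone-of-influence handling, wavelet mean fields and
    wavelet phasor mean fields with a random-phasor null model, spatial
    wavelet coherence between two spatiotemporal variables with
    Fourier-surrogate significance testing (including a fast
    frequency-domain scheme), multivariate wavelet linear models with an
    exact decomposition of model-explained synchrony into per-driver and
    pairwise interaction terms, an end-to-end driver-screening and
    modelling pipeline for resource-subsidy cascades, and a seeded
    generator of synthetic kelp-wrack-shorebird cascade data with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    zoo,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
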