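Package: frstdf
Title: Time-Domain Filtering for Field-Resolved Infrared Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing electro-optic sampling (EOS) traces from
    field-resolved infrared spectroscopy (FRS). Implements the referenced
    sample response (frequency-domain ratio), time-domain differencing, and
    time-domain filtering (TDF) of the referenced response, together with a
    synthetic measurement simulator (few-cycle excitation pulses, Lorentzian
    molecular responses in water, envelope-following multiplicative noise and
    an additive detection floor, cuvette-window echoes), SNR-versus-cutoff
    optimisation, Beer-Lambert concentration retrieval, path-length
    calibration, and cosine-similarity identification against spectral
    libraries. Delimited-text trace/spectrum formats and a minimal JCAMP-DX
    reader allow conventional FTIR spectra to be filtered with the same
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
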