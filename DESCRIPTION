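Package: difcr
Title: Two-Probe Diffuse In Vivo Flow Cytometry Signal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for enumerating rare fluorescently labeled circulating
    cells from two-probe diffuse in vivo flow cytometry (DiFC) recordings.
    Implements moving-median background subtraction, adaptive local-noise
    thresholding, peak detection, cross-probe coincidence matching with
    arterial/venous direction classification and speed estimation, and
    enumeration statistics (count rate, false-alarm rate, blood sampling
    rate, detectable fraction). Includes a ground-truthed synthetic
    recording generator with Poisson cell arrivals, Gaussian transit
    pulses, unbound-dye background clearance and band-limited noise, and a
    two-color flow-cytometry event simulator with quadrant gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
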