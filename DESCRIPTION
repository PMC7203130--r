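Package: psoctEntropy
Title: Polarimetric Entropy Analysis of Jones-Matrix PS-OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying melanin-driven polarization scrambling in
    polarization-sensitive optical coherence tomography (PS-OCT). Computes the
    noise-bias-corrected von Neumann entropy of local Jones matrices via
    Cloude-Pottier decomposition, builds en face entropy and intensity maps
    with layer-exclusion projection rules (above-membrane maximum for
    cultured-cell preparations, delineation-band projection excluding the
    choroid for retinal volumes), and summarises entropy in regions of
    interest against pigmentation. Includes a seeded Jones-matrix phantom
    simulator of melanin-bearing retinal pigment epithelium scenes so that
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
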