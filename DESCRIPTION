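Package: cochleostat
Title: Stereological Cytocochleograms and Simulated Noise-Induced Hearing
    Loss Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying noise-induced hearing loss in the mouse
    cochlea. Synthesizes violet and violet swept-sine exposure stimuli and
    verifies their spectral properties; generates flattened organ-of-Corti
    hair-cell maps with a tonotopic, level- and band-dependent lesion model;
    estimates inner and outer hair cell densities per 5% cochlear sector with
    unbiased counting frames, corner-point reference-area estimation and the
    Cochran ratio-estimator coefficient of error; assembles percentage
    cytocochleograms with a place-frequency axis; and simulates ABR/DPOAE
    cohorts with threshold detection, threshold-shift audiograms and
    structure-function correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
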