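Package: burstquant
Title: Simulation and Quantification of Neonatal Cortical Burst Activity and
    Apoptotic Cell Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spontaneous electrical activity and programmed
    cell death in the neonatal mouse neocortex. Provides a synthetic-data
    generator for local field potential (LFP) recordings with known ground-truth
    trough trains and for spatial Poisson maps of apoptotic cells; segmented-FFT
    mean power spectra and band-power summation; dual-band (4-30 Hz and
    30-100 Hz) trough detection with an 8-fold baseline-deviation threshold and
    8 ms cross-band deduplication; conversion of detected event trains into
    replay stimulation protocols; sectorized laminar quantification of
    apoptotic-cell density (six 0.55 mm sectors, layer bands I-IV, V, VI); and
    the associated statistical comparisons (two-group tests, two-way ANOVA with
    post-hoc correction). All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
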