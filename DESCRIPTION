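Package: parasip
Title: Single-Cell Stable-Isotope Probing of Fungal Parasitism on
    Nitrogen-Fixing Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying carbon and nitrogen fluxes between
    filamentous, N2-fixing cyanobacteria and their chytrid fungal
    parasites from secondary-ion mass spectrometry (SIMS) ion-count
    images. The package covers the full desk-scale workflow: simulation
    of Dolichospermum-like populations and Poisson ion-count image
    stacks, region-of-interest isotope-ratio quantification with
    counting-statistics quality control and instrument
    mass-fractionation correction, atom-percent-excess and single-cell
    carbon/nitrogen incorporation rates, paired host-sporangium
    transfer metrics, zero-inflated count models for bacterial
    colonization, and the population-level extrapolation of fixation
    loss and nitrogen fate under fungal epidemics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmmTMB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
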