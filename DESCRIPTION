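Package: magcyto
Title: Flow-Cytometry Physiology Toolkit for Magnetotactic Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis battery for single-cell flow-cytometry characterisation of
    Magnetospirillum gryphiswaldense MSR-1 and similar magnetotactic bacteria:
    viability classification by BOX/propidium-iodide quadrant gating,
    relative polyhydroxyalkanoate (PHA) and chelatable-iron quantification from
    dye fluorescence, optical-density-to-cell-count calibration, scatter-based
    morphology comparison, and the magneto-spectrophotometric C_mag statistic.
    Includes a synthetic-cytometer event generator (log-normal subpopulations,
    staining-saturation kinetics, Stern-Volmer iron quenching, paired
    optical-density readings) so every analysis stage is testable at desk scale,
    plus FCS 3.0/3.1 and annotated-CSV event input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
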