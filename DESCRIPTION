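Package: neutrondose
Title: Out-of-Field Photoneutron Organ Doses and Secondary-Cancer Risk in
    High-Energy Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts rem-meter measurements of neutron ambient dose
    equivalent H*(10) at the patient table of a high-energy (18 MV) linac
    into per-organ neutron equivalent doses for out-of-field organs, using
    distance-bin assignment and a tabulated neutron depth-dose curve, and
    aggregates them into effective dose, secondary fatal-cancer risk and
    genetic-effects projections with NCRP-116 tissue weighting factors and
    risk coefficients.  Includes composite-organ rules for skin, red bone
    marrow and bone surface, first-order uncertainty propagation, a
    synthetic-campaign generator with known ground truth, and a
    config-driven reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
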