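Package: phenopeat
Title: Process-Based Phenology Modelling for Whole-Ecosystem Warming Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits and compares process-based spring budburst and autumn
    senescence models to phenological transition dates observed in
    enclosure-scale warming and CO2-enrichment experiments on boreal
    peatlands. Provides a registry of 19 spring models (thermal-time,
    photo-thermal, alternating, sequential, parallel, unified and
    growing-season-index families) and 10 autumn models (chilling-degree-day
    families with photoperiod, water-table and CO2 extensions), bounded
    simulated-annealing parameter estimation over parallel chains, AIC-based
    model ranking with support classes, extraction of transition dates from
    daily canopy-greenness (green chromatic coordinate) series, mixed-effects
    temperature and CO2 sensitivity statistics, and a synthetic
    enclosure-experiment generator so the full analysis can be exercised and
    tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    nlme,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    geosphere,
    withr
Config/testthat/edition: 3
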