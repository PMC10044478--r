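Package: beefsys
Title: Farm-Level Bio-Economic Modelling of Beef Production Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A profit-maximising single-farm activity model for European beef
    production systems with monthly herd and feed accounting, a
    cradle-to-farm-gate greenhouse-gas inventory per kg beef carcass,
    net human-edible-protein efficiency and work-time indicators, scenario
    transforms for fast rotational grazing and system redesign
    (dairy-beef crossbreeding with sexed semen), and Latin-Hypercube
    sensitivity analysis. Ships synthetic fixtures for three stylised
    systems (Belgium, France-Italy, Germany) so the whole pipeline runs
    without external data. Includes a two-phase simplex solver exposing
    dual values, used for shadow-price-based economic allocation of
    emissions between milk and beef.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
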