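Package: marshmethane
Title: Valuing Avoided Methane Emissions from Salt Marsh Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An accounting pipeline for the methane-abatement benefit of
    salinity-restoring salt marsh restoration. Aggregates pre- and
    post-restoration salinity monitoring data and classifies restoration
    outcomes against the 18 psu threshold at which marsh methanogenesis is
    suppressed; converts successful restorations into avoided annual and
    cumulative methane emissions under configurable salinity-based emission
    factors; credits avoided emissions as Verified Carbon Units through a
    global-warming-potential table and prices them at a market rate; values
    them with an annual social-cost-of-methane schedule under selectable
    discount rates; and scales per-hectare results to a regional
    tidal-restriction inventory. Includes a seeded synthetic-data generator
    for salinity monitoring records and marsh inventories with known ground
    truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
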