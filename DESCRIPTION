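Package: reformprice
Title: Reformulation and Price Monitoring for Branded Food Label Databases
Version: 0.1.0
Authors@R: person("FLIP", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for monitoring nutrient reformulation and price change in
    packaged foods between two time-point snapshots of a branded food label
    database. Matches products across years by product code, retailer and
    container size, normalizes prices and nutrients to a per-100 g (or ml)
    basis, classifies nutrient changes into five Daily-Value-threshold
    reformulation groups, scores nutritional quality with the FSANZ Nutrient
    Profiling Scoring Criterion, and estimates the association between
    reformulation and price change with paired nonparametric tests and
    mixed-effects models. Includes a synthetic food-supply generator with
    known ground truth so the full pipeline is testable without proprietary
    label data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
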