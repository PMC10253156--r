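Package: fleetair
Title: Vehicle Fleet Emission Scenarios and Air Quality Health Impact
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up modelling of passenger-vehicle tailpipe CO2 and NOx
    emissions under fleet-composition and electrification scenarios, with
    downstream health impact assessment. Builds per-segment emission
    profiles from vehicle-model registration data, fits mass-emission
    regressions, calibrates a cohort stock-turnover survival schedule,
    projects annual and cumulative fleet emissions under substitution and
    electrification policies, converts NOx changes to urban background NO2
    reductions, and estimates and monetises life years gained with an
    IOMLIFET-style life table using a concentration-response function,
    inception lag, and discounted value-of-life-year valuation. Includes a
    synthetic-data module emulating the statistical structure of the UK
    2020 new-registration fleet and a national mortality schedule so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
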