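Package: foodswap
Title: Multicriteria Assessment of Meat and Milk Alternatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparing meat and milk alternatives with
    the animal-source foods they replace across nutritional, health,
    environmental, and cost domains. Implements a diet-level nutritional
    imbalance indicator with phytate-dependent zinc and absorption-adjusted
    iron requirements, a comparative risk assessment of diet-attributable
    mortality built on six nutrient risk factors and population impact
    fractions, benchmark-normalized environmental impact scores weighted by
    planetary-boundary contributions, CPI-deflated and PPP-converted cost
    accounting, calorie- or serving-conserving diet replacement scenarios,
    and a 0-100 multicriteria synthesis score. A seeded synthetic-data
    generator produces complete, internally consistent input bundles so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
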