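Package: ferroclim
Title: Dietary Iron Supply Losses Under Elevated Atmospheric CO2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the reduction in per-country dietary iron supply for
    children aged 1-5 and women of childbearing age when staple crops are
    grown under elevated atmospheric CO2 (550 ppm). Disaggregates national
    per-capita food supplies to age-sex groups using relative-intake
    factors with a dietary-energy fallback, fits skew-normal uncertainty
    distributions to reported crop effect intervals by quantile matching,
    propagates intake and effect uncertainty by Monte Carlo to per-country
    total percentage iron loss, classifies countries into risk categories
    by crossing loss tertiles with anemia prevalence, and implements a
    vegetarian counterfactual and a dietary-diversity statistic. Includes
    a synthetic-data generator producing complete, internally consistent
    input bundles so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
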