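Package: npmtv
Title: Nutrient-Profile Classification of TV Food Advertising to Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based decision engine for the WHO Eastern Mediterranean
    Region (EMR) nutrient profile model, classifying advertised food and drink
    products as permitted or not permitted for marketing to children, together
    with the descriptive exposure analytics used in television food-advertising
    content analyses: food-advertisement shares by program rating and study
    week, hourly advertisement frequencies against analyzed broadcast hours,
    food-category distributions, permitted/not-permitted shares under an
    18-category and an extended basis, health-claim and disclaimer shares, and
    intercoder percent agreement. Includes a seeded synthetic broadcast-log
    generator emulating a multi-channel children's-viewing-time sampling frame
    and a deterministic reference corpus for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
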