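Package: cartcea
Title: Cost-Effectiveness of Early Versus Deferred Antiretroviral Therapy
    Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cohort model comparing immediate ("early")
    versus deferred ("delayed") initiation of combination antiretroviral
    therapy (cART) for HIV-positive patients presenting with CD4 counts of
    250-350 cells/uL in a resource-limited setting. Maps baseline CD4 count
    to life expectancy by piecewise-linear interpolation, models the
    pre-treatment waiting period under biannual CD4 monitoring, computes
    discounted life-years, disability-adjusted life years (DALYs) averted,
    lifetime treatment and hospitalization costs, and the incremental
    cost-effectiveness ratio (cost per DALY averted), with one-way
    (tornado) sensitivity analysis and an individual-level microsimulation
    validator of the deterministic cohort engine.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
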