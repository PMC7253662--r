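Package: abxfund
Title: Comparing Direct and Prize-Based Public Funding of Antibiotic Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Monte Carlo valuation of staged antibiotic development projects
    and of the public cost of stimulating them. Samples hypothetical projects
    for six clinical indications from published per-phase time, cost and
    success-probability distributions, periodizes them into risk-adjusted
    discounted cashflow schedules, and values each project from four
    perspectives: the private developer, the developer under a phase- or
    market-entry reward, the prize-issuing benefactor, and an at-cost
    (direct) public funder subject to an operational inefficiency. Fits
    logistic incentive-response models linking prize size to the conditional
    probability of turning a no-decision into a go-decision, inverts them to
    size prizes for a target response, and runs the baseline, grid-sweep and
    scenario experiments comparing the per-market-approval cost of direct
    versus indirect funding.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
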