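Package: crclbce
Title: Cost-Effectiveness of Liquid-Biopsy Recurrence Surveillance in Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model and patient-level Monte Carlo
    microsimulation of colorectal cancer (CRC) recurrence surveillance with
    next-generation-sequencing liquid biopsy (NGS-LB) in Spain, France, and
    Germany. Provides age-dependent six-state transition models built from
    national (or synthetic Gompertz-Makeham) life tables and stage-specific
    recurrence, mortality, utility and three-tier cost parameters; accrues
    discounted life-years, QALYs and total direct treatment costs; computes
    incremental cost-effectiveness ratios against standard care with
    willingness-to-pay verdicts; and runs one-way tornado sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
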