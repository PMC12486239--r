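Package: msbrand
Title: Minimal Sufficient Balance Randomization for Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Covariate-adaptive randomization for two-arm randomized
    controlled trials using the minimal sufficient balance (MSB)
    algorithm: per-covariate imbalance tests cast votes for the arm that
    would reduce imbalance, and a biased coin favors the majority arm
    only when balance criteria trigger.  Includes the trigger-driven
    allocation workflow used with electronic data capture systems
    (parse a data-entry-trigger payload, check readiness, allocate,
    write back, audit, static back-up list with reconciliation), a
    CSV/JSON record store, balance reporting with standardized
    differences, and a Monte-Carlo enrollment simulator comparing MSB
    against simple randomization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
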