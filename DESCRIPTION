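Package: tacsim
Title: Simulation and Evaluation of Protocol-Based Tacrolimus Dose Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for evaluating recommendation sources against an
    institutional tacrolimus dose-adjustment protocol in simulated
    therapeutic drug monitoring. Provides a deterministic protocol engine
    (trough classification, percentage-band selection, dose-range
    computation, hold overrides, increment rounding and twice-daily
    splitting), a seeded stratified generator of structured dosing
    scenarios, mock recommendation agents with configurable error
    injection, a hierarchical error-classification grader, and paired
    evaluation statistics (agreement-rate reproducibility, McNemar tests,
    stratified adherence reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
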