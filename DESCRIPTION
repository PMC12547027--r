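Package: blindex
Title: Blinding Indices for Randomized Controlled Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation of blinding success in randomized controlled trials
    from treatment-guess questionnaires. Implements the James blinding index
    (disagreement beyond chance, with a jackknife confidence interval), the
    arm-specific Bang blinding indices and their study-level sum (multinomial
    contrast with asymptotic normal intervals, including a weighted form for
    five-level Likert responses), and the Simple blinding index (between-arm
    difference in the proportion guessing active treatment, with a
    Wilson-score/MOVER interval). Includes cross-tabulation input/output for
    2x2, 2x3, 2x5 Likert and multi-arm guess tables, table transformations
    (Likert collapsing, arm combining, "don't know" exclusion), cutoff-based
    interpretation reports, a scenario simulator with coverage and bias
    experiments, and a bundled set of example datasets from the
    blinding-assessment literature.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
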