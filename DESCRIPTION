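Package: f1screen
Title: One-Generation Dominant Modifier Screen Analysis for Drosophila
    Deficiency Kits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores one-generation (F1) dominant modifier screens in which a
    semilethal sensitized male class is counted against fully viable control
    female siblings. Provides polytene cytogenetic band parsing and interval
    algebra for deficiency breakpoints, per-line viability scoring (percent F1
    males, fold change versus a fixed baseline, suppressor/enhancer
    classification), submapping of modifier hotspots with overlapping smaller
    deletions down to candidate-gene intervals, and a generative binomial
    cross simulator for power analysis and effect-size recovery. Ships the
    screen and submapping tables of a Drosophila PAX7-FOXO1 deficiency screen
    as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
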