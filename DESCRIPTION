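Package: cupgrammar
Title: Action-Grammar Analysis of Seriated Nesting-Cup Manipulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses the object-action-location notation used to code
    combinatory object manipulation in seriated nesting-cup tasks, tracks
    the physical cup configuration event by event, classifies every
    combinatory action into nine manipulative categories (pairing, pot,
    subassembly, unit-unit, pile, pile sub, put, disassemble, other), and
    computes trial- and group-level summaries such as success rate,
    maximum nesting depth, hierarchical level and per-category percentages.
    Includes an agent-based simulator that generates coded trials with
    known ground-truth strategy intents for validating the full pipeline.
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
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
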