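Package: trialbasket
Title: Detection and Landscape Analysis of Basket Trials in Neurodegenerative Disease Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines clinical-trial registry exports (clinicaltrials.gov-style
    XML study records or flat one-row-per-trial tables) for "basket" trials
    that study a single drug agent across two or more neurodegenerative
    disorders (NDDs). Normalizes free-text condition names and eligibility
    criteria against a curated NDD vocabulary tolerant of spelling variants,
    applies a filter cascade (update window, interventional studies, multi-NDD
    rule with stage-variant folding, lexicon-based intervention
    classification), annotates agents with mechanism-of-action class
    (symptomatic vs disease-modifying) and CADRO target category, and
    aggregates the resulting trial-agent pairs into landscape summary tables.
    Includes a deterministic synthetic-registry generator with planted ground
    truth and packaged fixtures for reproducible testing without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    rlang,
    tibble,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
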