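Package: progsat
Title: Progression Saturation Scoring for Analog Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how close a medicinal-chemistry analog series is to
    chemical saturation. Single-site analog series are extracted from
    compound-activity data by RECAP single-cut matched-molecular-pair
    fragmentation, virtual candidate analogs are enumerated by recombining
    each series core with a substituent fragment library, and every series
    is placed in a constant seven-descriptor chemical reference space. Two
    complementary neighborhood scores -- a global score measuring how much
    of the candidate cloud falls inside neighborhoods of assayed analogs,
    and a local score relating active-analog counts to candidates inside
    active neighborhoods -- are z-normalized across the series ensemble and
    mapped to four lead-optimization stages (early, intermediate, late,
    saturated).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    igraph,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: OpenBabel (obabel on the PATH)
Config/testthat/edition: 3
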