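Package: turntiming
Title: Conversational Turn-Timing Analysis from Dual-Speaker Interval Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the timing of turn-taking in dyadic
    conversation from interval annotations of two speaker channels.
    Reads Praat TextGrid and delimited interpausal-unit (IPU) tables,
    canonicalises channels under a minimum-pause rule, classifies every
    between-speaker event as a silent gap, a between-overlap or a
    within-overlap, and measures Floor Transfer Offset (FTO) for every
    floor transfer. Provides descriptive summaries (group, dyad and
    dialogue-stage cells, modal histogram bins, FTO-by-transition-index
    curves, leave-one-dyad-out robustness checks), a Bayesian
    hierarchical Gaussian model of FTO with dyad random intercepts
    fitted by a blocked Gibbs sampler with full convergence
    diagnostics, and a seeded generator of synthetic dyadic dialogues
    with ground-truth transitions for validation and power analysis.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
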