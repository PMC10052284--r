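Package: decklanding
Title: Affordance-Based Modelling of Helicopter Ship-Deck Landing Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the affordance of deck-landing-ability: whether a
    helicopter with a fixed attempt lift can touch down on a sinusoidally
    heaving ship deck with a touchdown velocity below a critical value.
    Provides closed-form descent kinematics with a contact-time solver,
    deck-landing-ability landscapes and fixed-lift slices, safe-window
    extraction and the dimensionless affordance ratio pi, the trial
    protocol of a two-group (low-lifter/heavy-lifter) judgment experiment,
    an ecological head-up display computation, a synthetic noisy-threshold
    observer cohort, and the decision-analysis pipeline (attempt
    frequencies and sigmoid fits, touchdown-velocity distributions and
    unsafe-attempt rates, timing-error analysis, landscape overlays).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    readr,
    yaml,
    jsonlite,
    minpack.lm,
    png,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
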