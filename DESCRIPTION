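Package: whiskertask
Title: Analysis of Active Whisker-Touch Decision Making in a Three-Choice
    Pole Localization Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing head-fixed rodent pole-localization behaviour
    from tracked whisker time series. Extracts mechanosensory predictors from
    1 kHz whisker angle/curvature/pole-distance traces (touch episodes,
    protraction/retraction touch type via the Hilbert phase of whisking, and
    the dkappa95 bending-moment statistic), fits maximum-a-posteriori
    naive-Bayes classifiers of pole location and mouse choice under tenfold
    cross-validation with shuffle-based chance levels, and quantifies
    session-level behaviour: task performance against a 10,000-shuffle null,
    learning and asymptote criteria, choice perseveration, and the
    correct/error double dissociation between sensory and choice-history
    predictors. A seeded synthetic-session generator reproduces the task's
    statistical structure so the full pipeline is testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    signal,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
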