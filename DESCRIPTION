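Package: attencert
Title: Attention Effects on Choice Accuracy and Certainty in Perceptual Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for psychophysical experiments that
    dissociate the effects of selective attention on objective performance (choice
    accuracy) and subjective performance (choice certainty) in four-alternative
    motion-coherence discrimination. Provides a parametric synthetic observer,
    cue-validity trial scheduling, a PEST-style adaptive staircase, maximum-likelihood
    logistic psychometric fits with parametric-bootstrap (Monte-Carlo) model
    comparison, and z-standardized group statistics with robust outlier screening,
    rating-frequency checks and control-subset reruns.
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
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
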