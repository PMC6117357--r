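Package: bayestime
Title: Bayesian Observer Models of Multisensory Time Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for Bayesian psychophysics of
    interval timing. Generates duration-discrimination and duration-reproduction
    trials from a parameterized ideal observer whose sensory noise follows the
    scalar property (Weber's law) and whose estimates are attracted toward a
    Gaussian prior over durations (central tendency). Fits cumulative-normal
    psychometric functions to recover Weber fractions, quantifies central
    tendency as the slope of reproduced-on-stimulus regression, estimates prior
    widths by inverting the Bayesian slope formula, and compares two hierarchical
    architectures for audiovisual timing: prior integration within each modality
    followed by maximum-likelihood cue combination, versus cue combination
    followed by a single prior integration. Includes paired bootstrap tests,
    model-comparison statistics, and an end-to-end simulated-cohort experiment
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
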