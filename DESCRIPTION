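Package: ppsmap
Title: Visual-Tactile Peripersonal Space Mapping and Crossmodal Congruency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for visual-tactile multisensory
    psychophysics. Builds session plans for a crossmodal congruency (CCE) task
    and a dynamic peripersonal space (PPS) task, generates trial-level reaction
    time data with ex-Gaussian noise and a distance-dependent multisensory
    facilitation, cleans trials, computes congruency metrics, maps PPS via a
    time-matched approach-minus-receding subtraction and a bounded sigmoid fit
    of its size and gradient, and performs group inference with a
    proportional-odds cumulative probability model, bootstrap predictive-mean-
    matching multiple imputation with Rubin pooling, and Spearman correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
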