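Package: pulsetaxis
Title: Pulsatile Sensory Coding and Derivative-Adaptation Chemotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pulsatile calcium dynamics of chemosensory neurons in
    smooth chemical gradients, and agent-based simulation of chemotaxis
    strategies. Provides smooth-gradient stimulus design through a stirred
    mixing-chamber model (with inversion into pump schedules), calcium-trace
    normalization, pulse detection and exponential-decay fitting, a
    permutation test for animal-to-animal individuality of pulse parameters,
    first-derivative-adaptation statistics on neural traces and 2D
    trajectories (angular deviation and reversal detection), an agent-based
    simulator contrasting the classical biased random walk with a
    derivative-adapting strategy, and seeded synthetic-data generators that
    emulate the statistical structure all of these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
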