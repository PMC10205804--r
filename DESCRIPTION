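Package: cachesim
Title: Event-Driven Simulation and Likelihood-Free Fitting of Food-Caching Bird Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of food-caching corvids as continuous-time,
    event-driven agents with per-food motivational control (stomach and hunger
    dynamics), a seven-layer associative what-where-when memory with nightly
    systems consolidation, reward-modulated plasticity of caching preferences,
    and an episodic planning-by-replay control model. Experimental protocols
    are expressed in a small domain-specific language (three object types,
    eleven actions) and executed against simulated birds to produce summary
    result tables. Population hyperparameters are fitted by likelihood-free
    inference: a mixed Euclidean/quantized-p-value distance between summary
    datasets, k-nearest-neighbor log-likelihood estimates, and a CMA-ES
    optimizer with a simple adaptive repetition schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
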