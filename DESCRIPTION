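Package: adaptcode
Title: Orientation Coding Under Luminance and Contrast Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for luminance-contrast switching experiments in
    early visual cortex: generation and classification of rapid-grating
    stimulus schedules, simulation of orientation-tuned spiking neurons with
    condition-dependent gain and exponential adaptation, orientation
    reverse-correlation kernel estimation with difference-of-von-Mises tuning
    fits and selectivity criteria, bias-corrected mutual information between
    spike counts and orientation, shuffle-normalised peri-switch firing-rate
    and Fano-factor dynamics, linear population decoding of orientation, four-
    model gain/offset tuning-modulation comparison, and cumulative-Gaussian
    psychometric threshold estimation with bootstrap comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
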