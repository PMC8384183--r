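Package: capshift
Title: Simulated Compound Action Potential Recordings and Threshold-Shift
    Analysis for Middle-Ear Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying conductive hearing loss with compound
    action potential (CAP) recordings. Simulates complete air- and
    bone-conduction CAP studies (tone-burst stimuli, alternating-phase
    averaging, cochlear-microphonic artifact, band-limited recording
    noise, frequency-dependent transducer ceilings), estimates hearing
    thresholds with a windowed peak-to-peak signal-to-noise criterion
    including no-response censoring at the maximum transducer output,
    and analyses threshold shifts across ligament-severing conditions
    with unbalanced two-way ANOVA, Cohen's f effect sizes, Tukey-Kramer
    post hoc comparisons and cumulative threshold curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
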