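Package: tonebattery
Title: Simulation and Bayesian Evidence Analysis for Phonetic Tone-Training Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-session phonetic training experiments
    with binary trial-level outcomes, built around a high-variability
    tone-training design (three training conditions, pre/post perception and
    production test battery, individual aptitude measures). Provides a
    trial-level synthetic-data generator mirroring the full task battery;
    centred contrast coding and logistic mixed-effects model presets with an
    automatic random-effects fallback ladder; informed Bayes factors for a
    point null against a half-normal alternative with principled prior-scale
    derivation rules, conclusion categories, robustness regions and
    sample-size projection; aptitude scoring (pitch-contour accuracy and
    tonal-continuum categorisation slopes with an exclusion threshold); and
    inter-rater reliability statistics (Cohen's kappa with Landis-Koch labels,
    two-way mixed average-measures ICC with Cicchetti labels).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
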