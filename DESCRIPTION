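Package: vmmn
Title: Simulation and Detection of the Visual Mismatch Negativity in
    Oddball EEG Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying automatic visual change detection with the
    visual mismatch negativity (vMMN). Generates constrained passive-oddball
    stimulus schedules for fragmented-character experiments, simulates
    multichannel EEG with parameterised evoked components and group-dependent
    temporal-integration behaviour over 1/f background noise, preprocesses
    recordings (zero-phase band-pass filtering, epoching with a
    second-fragment time-zero convention, baseline correction, amplitude
    artifact rejection), forms opposite-condition difference waves, detects
    the vMMN with a consecutive-significant-t run criterion, measures peak
    latencies and amplitudes, and scores behaviour: task hit rates and
    two-alternative forced-choice accuracy, with repeated-measures ANOVA
    (Greenhouse-Geisser correction, partial eta squared) and Tukey HSD post
    hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    car,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
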