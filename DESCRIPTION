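Package: hippodesync
Title: Hippocampal Desynchrony Analysis for LFP, Spike and Calcium-Imaging Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline linking hippocampal neural desynchrony to
    hyperlocomotion in NMDA-receptor-antagonist (MK-801) mouse models of
    schizophrenia, with an aripiprazole treatment arm. Provides band-splitting
    and multitaper band-power estimation of local field potentials,
    regular-spiking / fast-spiking unit classification, spike-count-equalized
    spike-field coherence from spike-triggered LFP averages, calcium transient
    detection with decay-constant estimation, Fisher-corrected pairwise and
    speed-coupled correlations of calcium dynamics, open-field locomotion
    metrics, and group comparison reporting. A synthetic-session generator with
    vehicle, MK-801 and aripiprazole condition presets emulates the statistical
    structure the analyses assume so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
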