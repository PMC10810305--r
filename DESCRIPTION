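Package: exomyo
Title: Proportional Myoelectric Ankle Exoskeleton Control and Gait
    Adaptation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for treadmill walking with
    ankle exoskeletons under proportional myoelectric control. Provides a
    synthetic multi-subject gait and surface-EMG generator emulating a
    four-condition adaptation protocol (boots only, unpowered, powered,
    deadaptation), the causal EMG-driven controller chain (Butterworth
    filtering, rectification, envelope, subject-specific gain and
    threshold calibration, current saturation, current-to-torque
    transmission), stride segmentation and gait-cycle time normalization,
    exoskeleton/biological ankle moment-power-work decomposition,
    phase-restricted EMG root-mean-square metrics, and scalar plus
    curve-level inference (repeated-measures ANOVA with Tukey HSD,
    permutation-based one-dimensional statistical parametric mapping, and
    noncentral-t paired-test sample-size calculation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
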