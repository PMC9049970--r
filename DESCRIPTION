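Package: trrtools
Title: Simulation and Analysis of Task-Related Hemodynamic Responses
Version: 0.1.0
Authors@R: person("TRR", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing task-related hemodynamic
    responses (TRRs) in visual cortex: an adaptive-staircase behavioural
    simulator, generators for BOLD, pulse-oximetry, respiration, head-motion
    and pupillometry signals with arousal-coupled structure, double-gamma
    hemodynamic response function (HRF) evaluation and fitting, GLMM design
    construction from trial-onset, button-press and time-on-task inputs,
    nuisance projection and trial epoching, sinusoid/Fourier amplitude and
    circular phase-variability statistics, permutation tests with exact
    finite-sample p-value correction, a visual-field border artifact test,
    two-stage adaptive FDR, and cardiac/respiratory/pupil arousal metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
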