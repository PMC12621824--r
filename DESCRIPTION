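Package: patchforage
Title: Simulation and Analysis of Patch-Foraging Behavior, Striatal State
    Transitions, and Dopamine Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying temporal decision-making in a two-port
    patch-foraging task. Provides a generative task model with
    Marginal-Value-Theorem-optimal exit computation; seeded simulators for
    behavioral event logs, two-state Poisson spike trains, and two-channel
    fiber-photometry traces with known ground truth; behavioral analyses
    (exit-time hazard curves, linear stay/leave classification, projected
    exit-time regression); a sigmoid-based detector of discrete firing-rate
    state transitions; a population accumulation-to-threshold exit
    predictor; and a photometry pipeline (isosbestic motion correction,
    dF/F0, per-reward transient amplitude, mixed-effects amplitude model).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    lme4,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
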