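Package: bimanforce
Title: Closed-Loop Simulation and Analysis of Bimanual Isometric Force Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a closed-loop model of bimanual isometric force
    production in which visual feedback is withdrawn mid-trial and control
    falls back on delayed, noisy proprioceptive feedback of a slowly
    drifting internal force target. Provides the accompanying outcome
    pipeline for measured or simulated two-channel grip-force recordings:
    Butterworth low-pass preprocessing, percent force undershoot, root
    mean square error, Welch band power, and inter-hand magnitude-squared
    coherence over defined epoch windows. Includes dose-response sweeps
    over the proprioceptive feedback gain, sham versus stimulation
    condition comparisons, and a pre/post two-group statistical battery
    (paired t tests with Holm correction, change-score interaction tests,
    Cohen's d, intraclass correlation, baseline-adjusted ANCOVA, and
    change-score correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
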