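Package: curbwalk
Title: Optimal Push-Off Compensation for Walking Over an Uneven Step
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanics and optimal control of a point-mass inverted-pendulum
    walker negotiating a single raised or lowered step (a sidewalk curb),
    with push-off work as the only actuation cost. Solves the minimum-work
    multi-step compensation under total-time and boundary-speed constraints,
    together with alternative control strategies (no compensation, reactive,
    tight time regulation), and converts solutions to per-step body-speed
    trajectories. Includes a synthetic gait cohort generator emulating a
    walkway experiment with foot-mounted inertial sensing, a reconstruction
    pipeline (footfall detection, zero-velocity-update integration, stride
    tables, inter-foot detrending, per-step body speeds), and the
    statistical analyses used to compare human and model compensation
    patterns (pattern correlations with one-sample t-tests, step-height and
    speed scaling regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
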