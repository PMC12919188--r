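Package: comfeedback
Title: Delayed Center-of-Mass Feedback Models of Reactive Balance Torque
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and evaluating delayed center-of-mass (CoM)
    feedback models of the multi-joint torque response to standing-balance
    perturbations. The model reconstructs a joint torque trace as a
    quasi-linear sum of parallel feedback loops acting on half-wave-rectified,
    time-delayed CoM displacement, velocity and acceleration. The package
    provides signal primitives (zero-phase low-pass filtering, resampling,
    sample-quantized delays, rectification, windowing), a staged bounded
    least-squares fitting procedure with delay grid search, trial averaging
    and sinusoid-residual extraction, four cross-condition generalization
    protocols (direction, magnitude, continuous sinusoid, superimposed
    perturbation), and a closed-loop inverted-pendulum simulator that
    generates a full synthetic perturbation study from known ground-truth
    feedback parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
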