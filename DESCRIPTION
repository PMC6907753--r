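Package: dyadgame
Title: Differential-Game Models of Physically Coupled Dyadic Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of joint reaching by two players coupled
    through a virtual spring. Implements the dyad plant (point masses, spring,
    muscle-activation dynamics), per-group sensory models, feedback-Nash and
    no-partner linear-quadratic controllers, a per-player augmented Kalman
    observer that estimates the partner's motor command, a fictitious-play
    learning loop over a full experimental protocol, and the behavioral
    indicator pipeline (score, interaction force, via-point distances,
    interaction power and leadership indices) applied identically to simulated
    and recorded trials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    signal,
    data.table,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
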