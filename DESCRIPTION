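Package: reachadapt
Title: Adaptive Duration Tuning for Robot-Assisted Point-to-Point Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free implementation and simulator of an assist-as-needed
    adaptive training loop for robot-assisted upper-limb reaching. Provides
    minimum-jerk reference trajectories over a 13-segment virtual-cube
    workspace, lead/lag effort metrics computed from sampled end-effector
    positions, a bounded iterative duration-update rule with
    constant-optimum convergence detection, synthetic participant models
    that close the loop, and the dummy-coded interaction regression used to
    analyse condition effects on movement duration. Packaged fixtures
    transcribe the published session tables so the worked numeric examples
    can be reproduced without robot hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite,
    optparse
Config/testthat/edition: 3
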