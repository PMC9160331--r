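Package: hrlsim
Title: Homeostatic Reinforcement Learning Simulation of Sodium and Water
    Appetite
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulator for homeostatic reinforcement learning
    (HRL) models of sodium appetite and osmoregulation.  Reward is defined
    as drive reduction in a multi-dimensional homeostatic space; action
    values are learned with a Rescorla-Wagner rule and actions are chosen
    by a softmax policy.  Taste input can serve as a predictor of
    internal-state change, and a tonic parabrachial (LPBN) bias with
    chemogenetic (DREADD) cancellation acts at selection time only.  Ships
    declarative, seed-controlled builders for four canonical simulation
    experiments (sodium intake test, saltwater density preference,
    intragastric infusion / oral stimulation, two-bottle preference, and
    DREADD manipulation), cohort summaries, landmark-timing statistics,
    CSV/JSON/YAML input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
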