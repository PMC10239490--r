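Package: skiturn
Title: Musculoskeletal Simulation of Muscle and ACL Forces in Alpine Ski Turning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based estimation of lower-limb muscle forces and anterior
    cruciate ligament (ACL) loading during carved turning in alpine skiing.
    Provides a rigid-body skier model with Hill-type muscles in implicit form,
    a segmented ski with hypoplastic ski-snow contact, implicit-Euler forward
    simulation, a direct-collocation tracking optimizer with a
    tracking/effort/regularization objective, Newton-Euler intersegmental knee
    loads, a data-driven three-plane ACL force model, and generators for
    synthetic reference motions, noisy tracked channels and surface-EMG
    envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
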