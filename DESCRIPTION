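Package: kneefatigue
Title: Probabilistic Fatigue Modelling of Medial Knee Cartilage Under Gait Loading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to estimate the lifetime structural failure probability of
    medial tibiofemoral cartilage from gait loading. A reduction model converts
    lower-limb joint moments into muscle forces and a medial knee contact force
    via a frontal-plane moment balance; a discrete-element (elastic foundation)
    contact model presses a two-arc rigid femoral condyle into a bed of
    nonlinear springs on the tibial plateau to obtain cartilage strain fields;
    and a Weibull probabilistic fatigue model with damage, repair, and
    adaptation converts daily walking and running exposure into cumulative
    failure probability curves over an adult lifespan. Includes a seeded
    synthetic cohort generator, strain-life power-law fitting with Monte-Carlo
    calibration of the Weibull scatter parameters, paired t and TOST
    equivalence tests, and adaptation sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
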