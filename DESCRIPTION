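Package: skateGRF
Title: Ground Reaction Force Direction Estimation from Supporting-Leg
    Posture in Speed Skating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the direction of the ground reaction force (GRF)
    acting on an inline speed skater from the posture of the supporting
    leg, under the assumption that the reaction force acts perpendicular
    to the shoe sole.  Two orthogonal-triad estimators are provided, one
    built from the blade end markers and the ankle joint centre (Est1)
    and one from the blade end markers and the knee joint centre (Est2),
    together with the full verification pipeline: Butterworth smoothing
    with residual-method cutoff selection, stride phase segmentation and
    20/60/20 time normalisation, force-plate based agreement statistics
    (RMSE, ICC(2,1), Bland-Altman bias/precision/limits of agreement,
    fixed and proportional error detection), a regression-based
    per-component correction with leave-one-participant-out validation,
    and a synthetic stride simulator with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
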