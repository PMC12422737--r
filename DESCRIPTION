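Package: patchforage
Title: Accept-Reject Foraging Decisions from Animal Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies bacterial-patch encounters from worm
    midpoint trajectories and models the per-encounter decision to exploit a
    patch. Provides geometric encounter detection with distance thresholds,
    explore/exploit classification via a regularized two-component Gaussian
    mixture with a Silverman critical-bandwidth bimodality test,
    sensing/non-responding classification via replicated semi-supervised
    quadratic discriminant analysis with censored-feature marginalization, a
    soft-label logistic model of exploitation probability fitted by
    KL-divergence minimization with hierarchical (encounter x worm) bootstrap
    inference, bacterial patch density calibration, and an agent-based
    foraging simulator that supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
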