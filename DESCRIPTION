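Package: fcgrowth
Title: Bayesian Penalized Spline Growth Curves for Perinatal Functional
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling developmental trajectories of resting-state
    functional connectivity across the third trimester and early neonatal
    period. Computes seed-based intra- and internetwork connectivity
    strengths (Fisher-z) from node-level fMRI time courses with
    quality-control frame censoring and motion-based run exclusion, fits a
    Bayesian hierarchical penalized B-spline (P-spline) growth model with
    subject random intercepts and slopes and cohort-specific offsets and
    error variances by Gibbs sampling, and summarises posterior draws as
    anchored age estimates, age contrasts, 95% credible intervals and
    sign-error probabilities. Includes a synthetic-data generator emulating
    a three-cohort longitudinal/cross-sectional fetal-neonatal design and a
    principal-component composite of maternal mental-health instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    splines,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
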