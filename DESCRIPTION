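Package: brainagelink
Title: Brain-Aging Markers, PLS Correlation and Mediation for Population Cohorts
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline linking imaging markers of biological brain
    aging to cognitive and motor performance in large population cohorts.
    Computes relative brain age (cross-validated morphometry-based age
    prediction with a two-stage bias correction), logarithmized white matter
    hyperintensity load and the peak width of skeletonized mean diffusivity
    (PSMD); harmonizes cognitive and motor test scores into domain scores;
    runs partial least squares correlation between the imaging marker panel
    and clinical variables with permutation significance testing and
    bootstrap stability assessment; and performs bootstrap mediation of
    vascular-risk effects on performance through the imaging score.  A
    synthetic cohort generator with planted latent structure makes every
    stage testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
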