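Package: tkrshape
Title: 3D Bone Shape Vectors and Matched Case-Control Inference for Knee
    Osteoarthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies knee osteoarthritis structural severity from
    corresponded 3D bone point clouds via a statistical shape model: rigid
    generalized Procrustes alignment, principal-component shape space, and a
    discriminant "OA vector" score scaled so the mean non-OA training shape
    sits at -1 and the mean OA shape at +1. Provides the full downstream
    nested case-control workflow relating the score to total knee
    replacement: eligibility and control-knee selection rules,
    propensity-score nearest-neighbour matching without replacement with
    standardized-difference balance diagnostics, paired t-tests, conditional
    logistic regression for 1:1 matched pairs fitted from the conditional
    likelihood, AIC model comparison, tertile odds ratios, and exploratory
    stratified analyses. A seeded synthetic cohort generator emulating the
    structure of an OAI-like study (latent OA severity driving bone shape,
    Kellgren-Lawrence grade and pain; confounded surgery outcomes;
    test-retest shape replicates) lets every stage run end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
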