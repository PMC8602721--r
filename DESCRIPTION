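Package: MechanoHeal
Title: Mechano-Regulated Bone-Healing Simulation and Explainable Neural
    Surrogates for Dental Implant Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates peri-implant bone healing on a structured pixel grid
    with a mechano-regulatory tissue-differentiation loop (quasi-static
    elasticity under an occlusal micro-displacement, Darcy fluid flow from a
    one-step consolidation solve, stem-cell diffusion, biophysical stimulus
    S = gamma/a + nu/b, phenotype classification and material blending with
    history smoothing).  Provides a multi-network neural surrogate for the
    per-day field solves and phenotype updates (an encoder-decoder field
    regressor, a per-pixel focal-loss classifier, a structured denoiser and a
    random-forest resorption corrector) with an autoregressive 35-day rollout
    from the day-0 state, Deep Taylor decomposition relevance propagation for
    attribution analyses, and bone-implant performance metrics (tissue
    fractions, bone area, bone-implant contact, marginal bone loss) plus
    Pearson and ROC/AUC evaluation of surrogate fidelity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
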