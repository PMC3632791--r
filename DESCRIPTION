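Package: sacdisp
Title: Trans-Saccadic Displacement Perception and Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the perceptual matching of visual space
    across saccadic eye movements and its disruption after focal thalamic
    damage. Implements the adaptive STEP/BLANK intrasaccadic displacement
    task with interleaved one-up-one-down staircases, a generative observer
    model of corollary-discharge monitoring (motor gain and noise,
    corollary-discharge gain, noise and error coupling, condition-dependent
    decision noise), synthesis of 500 Hz eye-position traces and of lesion
    cohorts with a planted critical region, velocity-criterion saccade
    detection and targeting-error metrics, maximum-likelihood cumulative-
    Gaussian psychometric fitting (PSS, JND, 75 percent-correct threshold),
    individual deficit classification (relative threshold, directional
    asymmetry, oculomotor error-attribution), and voxel-based lesion-symptom
    mapping with the Liebermeister quasi-exact test, subtraction and power
    maps, and atlas-label association.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    RNifti
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
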