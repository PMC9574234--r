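Package: wandertap
Title: Behavioral, Pupillometric and fMRI Markers of Mind Wandering in
    Paced Finger Tapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for the finger-tapping
    random-sequence generation task (FT-RSGT) with experience sampling.
    Generates synthetic sessions from an explicit latent attentional-state
    process; computes behavioral variability (SD of inter-tap intervals) and
    approximate entropy of binary tap sequences; preprocesses and deconvolves
    pupil traces into tonic and phasic components with a pupil-response
    function and non-negative least squares; fits Bayesian hierarchical
    ordered probit regressions of thought-probe responses with posterior
    means, highest-density intervals, evidence ratios and Bayesian R2; and
    builds fMRI design matrices, mass-univariate GLMs, thresholded z-maps,
    atlas-overlap percentages and Dice coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pracma,
    splines,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
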