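Package: speckleGG
Title: Generalized Gamma Modeling of Ultrasound Speckle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the three-parameter
    Generalized Gamma (GG) distribution for ultrasonic envelope data via a
    profile-likelihood method, together with reference estimators (Stacy
    moments, a chi-squared grid heuristic, and an iterative log-scale ML),
    EM fitting of Generalized Gamma mixture models (two M-step variants)
    and their constrained Gamma/Nakagami/Rayleigh special cases, a B-mode
    speckle phantom simulator based on the random-walk scatterer model,
    histogram Kullback-Leibler and Kolmogorov-Smirnov goodness-of-fit
    measures with a multi-family comparison harness, and posterior
    tissue-probability applications: probability-driven oriented
    anisotropic diffusion (POSRAD), loopy-belief-propagation spatial
    coherence, and maximum-posterior classification.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
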