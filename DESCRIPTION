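Package: diffprint
Title: Diffusional Fingerprinting of Single-Particle Trajectories with
    Trajectory-Based Microrheology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 20-feature diffusional fingerprints from 2-D
    single-particle tracking trajectories: classical motion descriptors
    (power-law MSD fit, fractal dimension, efficiency, trappedness,
    Gaussianity, kurtosis), hidden-Markov state occupancies and dwell
    times on step-length sequences, and passive microrheology via the
    generalized Stokes-Einstein relation (creep compliance, complex,
    storage and loss moduli, viscosity). Provides a labeled motion
    simulator (Brownian, fractional Brownian, confined, directed,
    immobile, state-switching), a seven-classifier panel with
    cross-validated evaluation and tree-SHAP feature attributions,
    diffusion-mode classification by the MSD scaling exponent, and
    feature-wise class-similarity metrics (kernel-density area overlap,
    symmetrized Kullback-Leibler divergence, cosine similarity,
    Euclidean distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    class,
    e1071,
    nnet,
    randomForest,
    rpart,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
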