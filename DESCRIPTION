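Package: brainstates
Title: Brain-State Classification from Parcellated Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature engineering and supervised classification of brain states
    (baseline versus atypical) from parcellated resting-state fMRI time series.
    Computes 324 features per scan across five families: Pearson connectivity
    summaries with and without global signal regression, graph-theoretic
    metrics (efficiency, clustering, Newman modularity, participation
    coefficient) on density-thresholded binary graphs, and cortical-gradient
    features from diffusion-map embeddings of normalized-angle affinity
    matrices aligned by Procrustes rotation. Trains linear support vector
    machines under repeated nested cross-validation with grid hyperparameter
    search, combines them by feature integration, hard voting and soft voting,
    and evaluates balanced accuracy (with threshold search), AUC,
    cross-condition transfer and absolute-coefficient feature importance.
    Includes a factor-model generator of synthetic paired cohorts with planted
    discriminative effects for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
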