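Package: cbpm
Title: Connectome-Based Phenotype Prediction Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking the prediction of individual phenotype
    scores (big-five personality traits and a cognition composite) from
    structural connectomes. Builds number-of-streamlines (NOS), fractional
    anisotropy (FA) and mean diffusivity (MD) weighted connectomes from
    streamline sets and parcellation label volumes; implements four feature
    classes (whole-brain edges, most-correlated edges, principal components,
    regional connectivity profiles) with strictly train-set-fitted global
    min-max normalization; runs ridge regression under repeated nested
    5-fold cross-validation with permutation baselines; contrasts post-hoc
    best-of feature selection against in-loop selection to quantify
    selection-induced optimism; and projects regional prediction accuracies
    onto voxelwise brain maps averaged across parcellations. Ships a seeded
    synthetic-data generator (parcellations, scalar maps, streamlines,
    connectome populations, cohorts with planted edge-to-target signal) so
    every stage is testable end to end without restricted-access imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
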