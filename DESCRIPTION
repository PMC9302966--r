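Package: oneshotadapt
Title: Trial-Level Analysis of Compensation and One-Shot Adaptation to
    Formant Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing speech sensorimotor adaptation experiments in
    which a speaker's first-formant (F1) auditory feedback is unpredictably
    shifted up or down on a subset of trials. Converts per-trial F1
    trajectories to deviations from participant- and word-specific baseline
    trajectories, computes windowed compensation and one-shot adaptation
    responses at the trial and participant level, and carries out the
    associated inference: direction effects via linear mixed-effects models
    with Satterthwaite degrees of freedom, paired and one-sample t-tests with
    effect sizes, cluster-based permutation tests over the trajectory
    timecourse, compensation-adaptation relationship models, and
    Fisher-aggregated per-participant correlations. Includes a synthetic
    experiment generator with known ground truth for validation and power
    exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
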