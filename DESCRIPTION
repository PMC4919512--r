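Package: multitraj
Title: Multifactorial Biomarker Trajectory Modelling of Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-biomarker aging and disease trajectories from
    longitudinal multimodal cohorts and derives a data-driven temporal ordering
    of pathological factors. Biomarkers are standardized and fitted with linear
    fixed- or mixed-effects models (robust regression and maximum-likelihood
    mixed models, selected by BIC), marginalized over nuisance covariates to
    functions of age and clinical disease state, and evaluated along clinical
    transitions on a weekly 30-year age grid. Abnormality of each biomarker
    relative to healthy aging is summarized as normalized area-under-curve
    indices, pairwise factor dominance matrices, regional vulnerability weights,
    and vulnerability-weighted factor curves, with subject-level bootstrap
    confidence bands. Includes a synthetic longitudinal cohort generator with
    planted factor orderings, clinical converters and outliers, plus a
    three-step cohort quality control (converter removal, diagnosis-likelihood
    filtering, Mahalanobis outlier detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
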