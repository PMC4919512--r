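# multitraj

Multifactorial biomarker trajectory modelling of disease progression.

`multitraj` is for researchers studying neurodegenerative disease with
longitudinal multimodal cohorts: several imaging-derived biological factors
(e.g. amyloid deposition, glucose metabolism, cerebral blood flow, resting
functional activity, grey-matter structure) measured per brain region at
repeated visits, plus scalar biomarkers (cognitive scores, CSF/plasma
analytes). It answers the question *in what temporal order do the factors
become abnormal as the disease progresses?* without assuming the ordering a
priori.

## The model

Each standardized biomarker observation is modelled as

    y_jm = x'_jm β + b_j + b_age,j · age_jm + ε_jm

with x = (1, age, DS, sex, edu, apoe4, all 10 pairwise interactions), so 16
fixed coefficients β, subject random intercept b_j and age slope b_age,j,
and Gaussian noise ε. DS is the ordinal clinical state 1–4 (HC, EMCI, LMCI,
dementia) used numerically. Per biomarker, three variants — purely fixed
effects (robust bisquare regression), random intercept, random
intercept + age slope (both ML) — are compared by BIC. After a three-step
quality control (converter removal, within-group diagnosis-likelihood
filtering at the 10th percentile, group-wise Mahalanobis outlier removal at
P < 0.05), the fitted predictor is marginalized over sex, education and
apoe4, leaving g(age, DS), which is evaluated on a weekly age grid (1,560
points, ages 40–70) along each clinical transition. The abnormality of a
biomarker is A(t) = |g_diseased(t) − g_healthy(t)|; its total abnormality
index is the area under A normalized by the set-wide maximum K (so the most
abnormal biomarker scores 1, Σ-intermediate indices truncate at the EMCI and
LMCI time points). Factor ordering comes from a pairwise dominance matrix
across regions and time points and from vulnerability-weighted normalized
factor curves, with subject-level bootstrap confidence bands (B = 500).

A synthetic cohort generator with planted factor orderings, clinical
converters and outliers makes every stage testable against known ground
truth. See the vignette `vignettes/progression-modelling.Rmd` for the
modelling details and design decisions.

## Worked example

```r
library(multitraj)

cfg <- synthetic_config(n_subjects = 200, n_visits = 3, n_regions = 4,
                        noise_sd = 1, seed = 42)
sim <- generate_cohort(cfg)
paste(sim$truth$planted_factor_order, collapse = " > ")
#> "vascular > amyloid > metabolic > functional > structural"

qc  <- run_qc(sim$cohort)
qc$report$sizes
#>                    step n_subjects n_records
#> 1                 input        200     14400
#> 2     remove_converters        200     14400
#> 3 filter_low_likelihood        182     13104
#> 4       detect_outliers        182     12491

std <- standardize_biomarkers(qc$cohort)
res <- progression_analysis(std$cohort,
                            variants = c("fixed_robust", "mixed_intercept"))
head(res$index_table[order(-res$index_table$total_index),
                     c("biomarker_id", "total_index", "emci_index",
                       "lmci_index")], 4)
#>     biomarker_id total_index emci_index lmci_index
#> 23  vascular.r03   1.0000000 0.09635436  0.4149309
#> 24  vascular.r04   0.9363938 0.10528783  0.4186632
#> 21  vascular.r01   0.8207400 0.08042692  0.3432405
#> 22  vascular.r02   0.7932402 0.09081906  0.3579137

res$hierarchy
#> <hierarchical_matrix> 4 regions x 1560 time points
#> ordering: vascular > amyloid > metabolic > functional > structural
#>            vascular amyloid metabolic functional structural
#> vascular        0.0    11.0       7.6        1.1          0
#> amyloid        89.0     0.0      39.8       16.0          0
#> metabolic      92.4    60.2       0.0       12.6          0
#> functional     98.9    84.0      87.4        0.0          0
#> structural    100.0   100.0     100.0      100.0          0
```

Reading the output: the QC table shows how many subjects/records each step
retained (18 subjects fell below their group's 10th likelihood percentile;
613 record values were flagged as outliers). In the index table, the most
abnormal biomarker scores exactly 1 and the regional vascular biomarkers
dominate, as planted. Entry (i, j) of the hierarchical matrix is the
percentage of region–time points at which factor j exceeds factor i in
abnormality — e.g. amyloid exceeds vascular at only 11% of them — and the
recovered ordering `vascular > amyloid > metabolic > functional >
structural` matches the planted ground truth.

For confidence bands, wrap the same cohort in the bootstrap:

```r
bt <- bootstrap_pipeline(std$cohort, B = 500, seed = 1,
                         variants = "fixed_robust")
head(bt$summaries$indices)   # mean / 2.5% / 97.5% per biomarker index
```

A file-based run (`run_all(run_config(...))`) writes every intermediate
table, the resolved configuration and a run log to a results directory; a
subcommand CLI over the same stages lives at `inst/cli/multitraj.R`
(simulate, qc, fit, trajectories, abnormality, ordering, bootstrap,
run-all).

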