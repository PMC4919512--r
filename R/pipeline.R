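# End-to-end post-QC analysis: fit every biomarker, marginalize, generate
# trajectories over all clinical transitions, compute abnormality curves and
# indices, and derive the multifactorial ordering. This function is the unit
# the bootstrap engine resamples.

#' Run the progression analysis on a quality-controlled, standardized cohort
#'
#' Executes fit (BIC-selected model variants) -> marginalize -> trajectories
#' -> abnormality curves/indices -> ordering. The cohort is expected to have
#' passed quality control ([run_qc()]) and standardization
#' ([standardize_biomarkers()]).
#'
#' @param cohort standardized cohort data.frame.
#' @param variants model variants to try, see [fit_biomarker()].
#' @param weighting covariate marginalization weighting, see [marginalize()].
#' @param shape disease-state path shape, see [ds_path()].
#' @param grid age grid, see [age_grid()].
#' @param sigmoid_params sigmoid DS path parameters.
#' @param factor_names imaging factor names.
#' @param domains covariate domains; computed from `cohort` when NULL. Pass
#'   fixed domains when resampling so replicates share one marginalization.
#' @param k_scope,groups normalization scope for the abnormality indices, see
#'   [abnormality_index_table()].
#' @return a `progression_result` list: `fits`, `predictors`, `trajectories`,
#'   `curves`, `index_table`, and (when imaging biomarkers are present)
#'   `hierarchy`, `vulnerability`, `factor_curves`, `ranking`,
#'   `factor_ranking`.
#' @export
progression_analysis <- function(cohort,
                                 variants = c("fixed_robust",
                                              "mixed_intercept",
                                              "mixed_intercept_slope"),
                                 weighting = c("uniform", "empirical"),
                                 shape = c("linear", "sigmoid"),
                                 grid = age_grid(),
                                 sigmoid_params = list(midpoint = 55,
                                                       width = 20),
                                 factor_names = c("vascular", "amyloid",
                                                  "metabolic", "functional",
                                                  "structural"),
                                 domains = NULL,
                                 k_scope = c("all", "group"),
                                 groups = NULL) {
  weighting <- match.arg(weighting)
  shape <- match.arg(shape)
  k_scope <- match.arg(k_scope)
  validate_cohort(cohort)
  fits <- fit_all_biomarkers(cohort, variants)
  domains <- domains %||% covariate_domains(cohort)
  predictors <- lapply(fits, marginalize, domains = domains,
                       weighting = weighting)
  trajectories <- trajectory_set(predictors, TRANSITIONS, shape, grid,
                                 sigmoid_params)
  curves <- abnormality_curves(trajectories)
  load_curves <- curves[curves$transition == "HC-LOAD", , drop = FALSE]
  stage_ages <- stage_ages_from_path(shape, grid, sigmoid_params)
  index_table <- abnormality_index_table(load_curves, stage_ages, k_scope,
                                         groups)
  out <- list(fits = fits, predictors = predictors,
              trajectories = trajectories, curves = curves,
              index_table = index_table, stage_ages = stage_ages)

  meta <- parse_biomarker_ids(unique(load_curves$biomarker_id), factor_names)
  imaging_ids <- meta$biomarker_id[meta$imaging]
  if (length(imaging_ids)) {
    img <- load_curves[load_curves$biomarker_id %in% imaging_ids, ,
                       drop = FALSE]
    scal <- load_curves[!(load_curves$biomarker_id %in% imaging_ids), ,
                        drop = FALSE]
    present <- unique(meta$factor[meta$imaging])
    fac <- factor_names[factor_names %in% present]
    out$hierarchy <- hierarchical_matrix(img, fac)
    out$vulnerability <- regional_vulnerability(
      index_table[index_table$biomarker_id %in% imaging_ids, , drop = FALSE],
      fac)
    out$factor_curves <- factor_average_curves(img, out$vulnerability,
                                               scalar_curves = scal,
                                               factor_names = fac)
    out$ranking <- rank_factors(out$factor_curves)
    out$factor_ranking <- out$ranking[out$ranking %in% fac]
  }
  class(out) <- "progression_result"
  out
}
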