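# Shared builders for small in-code fixtures.

# One-biomarker config with short knobs; defaults keep everything tiny.
tiny_config <- function(n_subjects = 20, n_visits = 3, n_regions = 1,
                        factor_names = "vascular",
                        scalar_biomarker_names = character(0),
                        noise_sd = 0, random_effect_sd = c(0, 0),
                        seed = 1,
                        ds_effects = stats::setNames(
                          seq(1.25, by = -0.25,
                              length.out = length(factor_names)),
                          factor_names),
                        ...) {
  synthetic_config(n_subjects = n_subjects, n_visits = n_visits,
                   n_regions = n_regions, factor_names = factor_names,
                   scalar_biomarker_names = scalar_biomarker_names,
                   ds_effects = ds_effects,
                   noise_sd = noise_sd, random_effect_sd = random_effect_sd,
                   seed = seed, ...)
}

# Single-visit cohort of scalar biomarkers from a subjects x biomarkers value
# matrix; covariates are deterministic fillers.
scalar_cohort <- function(values, ds = rep(1, nrow(values)),
                          biomarkers = sprintf("b%02d", seq_len(ncol(values)))) {
  ns <- nrow(values)
  subjects <- sprintf("P%03d", seq_len(ns))
  df <- expand.grid(biomarker_id = biomarkers, subject_id = subjects,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(df$subject_id, subjects)
  j <- match(df$biomarker_id, biomarkers)
  data.frame(subject_id = df$subject_id, visit = 1L,
             age = 50 + (i %% 7), sex = i %% 2, education = 10 + (i %% 5),
             apoe4 = i %% 3, ds = ds[i],
             biomarker_id = df$biomarker_id,
             value = values[cbind(i, j)], stringsAsFactors = FALSE)
}

# A random 16-coefficient vector shaped like a fitted model.
random_fit <- function(seed, biomarker_id = "b") {
  set.seed(seed)
  beta <- stats::setNames(stats::rnorm(16, 0, 0.5), multitraj::design_columns())
  structure(list(biomarker_id = biomarker_id, variant = "fixed_robust",
                 beta = beta, random_sd = c(intercept = 0, age_slope = 0),
                 residual_sd = 1, log_likelihood = -10, k = 17, n_obs = 100,
                 bic = 17 * log(100) + 20, messages = character(0)),
            class = "biomarker_fit")
}

# Evaluate the full 16-term fixed-effects predictor directly (oracle).
predict_full <- function(beta, age, ds, sex, education, apoe4) {
  X <- multitraj::build_design(data.frame(age = age, ds = ds, sex = sex,
                                          education = education,
                                          apoe4 = apoe4))
  drop(X %*% beta)
}

# Constant abnormality curve on a grid.
const_curve <- function(id, height, grid = multitraj::age_grid(50)) {
  data.frame(biomarker_id = id, transition = "HC-LOAD", age = grid,
             value = height, stringsAsFactors = FALSE)
}
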