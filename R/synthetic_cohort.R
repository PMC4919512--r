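#' Configuration for the synthetic longitudinal cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' emulates a longitudinal multimodal aging cohort: five imaging-derived
#' biological factors measured on a set of grey-matter regions plus scalar
#' biomarkers (cognition, CSF/plasma analytes), observed over repeated visits
#' on subjects spanning four clinical groups (DS 1 = HC, 2 = EMCI, 3 = LMCI,
#' 4 = LOAD). Every biomarker value is drawn from the linear model
#' `y = x' beta + b0_subject + b1_subject * age + noise`, where `x` holds an
#' intercept, the five risk factors (age, DS, sex, education, apoe4 allele
#' count) and their ten pairwise interactions.
#'
#' A temporal factor ordering is planted through factor-specific `|beta_DS|`
#' magnitudes (`ds_effects`): under this linear model the abnormality-curve
#' magnitude of a biomarker is monotone in its DS effect, so downstream
#' ordering analyses can be checked against `planted_factor_order`.
#'
#' @param n_subjects number of subjects.
#' @param n_visits visits per subject (1 year apart).
#' @param n_regions grey-matter regions per imaging factor (default 78).
#' @param factor_names names of the imaging factors.
#' @param scalar_biomarker_names names of scalar (non-regional) biomarkers.
#' @param age_range baseline age range in years; ages are drawn uniformly.
#' @param group_proportions length-4 simplex of clinical group probabilities
#'   over DS 1..4.
#' @param ds_effects named vector of per-factor DS fixed-effect magnitudes in
#'   standardized units; names must cover `factor_names` and
#'   `scalar_biomarker_names`. Used only when `beta_true` is NULL.
#' @param beta_true optional full coefficient matrix (biomarkers x 16) with
#'   rownames equal to the biomarker ids and columns in [design_colnames()]
#'   order; overrides `ds_effects`.
#' @param random_effect_sd length-2: subject random-intercept sd and random
#'   age-slope sd (per year).
#' @param noise_sd residual sd of the observation noise.
#' @param converter_fraction fraction of subjects planted as clinical
#'   converters (diagnosis increases at a later visit), in [0, 1).
#' @param outlier_fraction fraction of records planted as gross outliers,
#'   in [0, 1).
#' @param outlier_magnitude outlier shift in within-group sd units (> 0).
#' @param sex_prob probability of sex = 1.
#' @param education_range integer range of years of education.
#' @param apoe4_probs probabilities of carrying 0, 1 or 2 apoe4 alleles.
#' @param seed integer root seed; all randomness flows from it through
#'   independent named streams (cohort, converters, outliers).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 200,
                             n_visits = 4,
                             n_regions = 78,
                             factor_names = c("vascular", "amyloid",
                                              "metabolic", "functional",
                                              "structural"),
                             scalar_biomarker_names = c("mmse", "csf_abeta42",
                                                        "csf_tau", "csf_ptau"),
                             age_range = c(40, 70),
                             group_proportions = c(0.4, 0.2, 0.2, 0.2),
                             ds_effects = NULL,
                             beta_true = NULL,
                             random_effect_sd = c(0.5, 0.02),
                             noise_sd = 1,
                             converter_fraction = 0,
                             outlier_fraction = 0,
                             outlier_magnitude = 6,
                             sex_prob = 0.5,
                             education_range = c(6, 20),
                             apoe4_probs = c(0.6, 0.3, 0.1),
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_visits >= 1)
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (abs(sum(group_proportions) - 1) > 1e-12 || length(group_proportions) != 4 ||
      any(group_proportions < 0))
    stop("group_proportions must be a length-4 simplex summing to 1")
  if (length(random_effect_sd) != 2 || any(random_effect_sd < 0))
    stop("random_effect_sd must be two non-negative values")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (converter_fraction < 0 || converter_fraction >= 1)
    stop("converter_fraction must lie in [0, 1)")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must lie in [0, 1)")
  if (outlier_magnitude <= 0) stop("outlier_magnitude must be > 0")
  if (length(age_range) != 2 || diff(age_range) <= 0)
    stop("age_range must be (min, max) with min < max")

  if (is.null(ds_effects)) {
    ds_effects <- c(vascular = 1.25, amyloid = 1.00, metabolic = 0.75,
                    functional = 0.50, structural = 0.25,
                    mmse = 1.10, csf_abeta42 = 0.45, csf_tau = 0.40,
                    csf_ptau = 0.35)
  }
  all_names <- c(factor_names, scalar_biomarker_names)
  if (is.null(beta_true)) {
    missing_fx <- setdiff(all_names, names(ds_effects))
    if (length(missing_fx))
      stop("ds_effects missing entries for: ", paste(missing_fx, collapse = ", "))
  }

  cfg <- list(n_subjects = as.integer(n_subjects),
              n_visits = as.integer(n_visits),
              n_regions = as.integer(n_regions),
              factor_names = factor_names,
              scalar_biomarker_names = scalar_biomarker_names,
              age_range = age_range,
              group_proportions = group_proportions,
              ds_effects = ds_effects,
              beta_true = beta_true,
              random_effect_sd = random_effect_sd,
              noise_sd = noise_sd,
              converter_fraction = converter_fraction,
              outlier_fraction = outlier_fraction,
              outlier_magnitude = outlier_magnitude,
              sex_prob = sex_prob,
              education_range = education_range,
              apoe4_probs = apoe4_probs,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Column order of the fixed-effects design matrix
#'
#' Intercept, the five main risk factors (age, ds, sex, education, apoe4),
#' then their ten unordered pairwise interactions — 16 columns in total.
#' @return character vector of 16 column names.
#' @export
design_columns <- function() design_colnames()

default_beta_true <- function(config) {
  if (!is.null(config$beta_true)) {
    bt <- as.matrix(config$beta_true)
    if (ncol(bt) != 16)
      stop("beta_true must have 16 columns (intercept + 5 mains + 10 interactions)")
    colnames(bt) <- design_colnames()
    return(bt)
  }
  ids <- c(imaging_biomarker_ids(config$factor_names, config$n_regions),
           config$scalar_biomarker_names)
  meta <- parse_biomarker_ids(ids, config$factor_names)
  key <- ifelse(meta$imaging, meta$factor, meta$biomarker_id)
  bt <- matrix(0, nrow = length(ids), ncol = 16,
               dimnames = list(ids, design_colnames()))
  bt[, "age"] <- 0.02
  bt[, "ds"] <- config$ds_effects[key]
  bt[, "sex"] <- 0.10
  bt[, "education"] <- -0.01
  bt[, "apoe4"] <- 0.15
  bt
}

#' Generate a synthetic longitudinal multimodal cohort
#'
#' Draws subject-level covariates and clinical groups, then biomarker values
#' from the linear fixed + random effects model described in
#' [synthetic_config()]. Diagnosis is constant within subject; converters and
#' outliers are planted afterwards (via [plant_converters()] and
#' [plant_outliers()]) when the corresponding config fractions are positive,
#' using independent random streams so the core cohort draws are unaffected.
#'
#' @param config a [synthetic_config()] object.
#' @return a list with elements `cohort` (tidy data.frame, one row per
#'   subject-visit-biomarker, columns subject_id, visit, age, sex, education,
#'   apoe4, ds, biomarker_id, value) and
#'   `truth` (a `ground_truth` list: `planted_factor_order`, `converter_ids`,
#'   `outlier_records`, `beta_true`, `random_effect_sd`, `noise_sd`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  beta <- default_beta_true(config)
  ids <- rownames(beta)
  ns <- config$n_subjects
  nv <- config$n_visits
  nb <- length(ids)

  dat <- with_seed(stream_seed(config$seed, "cohort"), {
    subj_ds <- sample(1:4, ns, replace = TRUE, prob = config$group_proportions)
    subj_sex <- stats::rbinom(ns, 1, config$sex_prob)
    subj_edu <- sample(seq(config$education_range[1], config$education_range[2]),
                       ns, replace = TRUE)
    subj_apoe <- sample(0:2, ns, replace = TRUE, prob = config$apoe4_probs)
    subj_age0 <- stats::runif(ns, config$age_range[1], config$age_range[2])
    b0 <- matrix(stats::rnorm(ns * nb, 0, config$random_effect_sd[1]), ns, nb)
    b1 <- matrix(stats::rnorm(ns * nb, 0, config$random_effect_sd[2]), ns, nb)
    eps <- matrix(stats::rnorm(ns * nv * nb, 0, config$noise_sd), ns * nv, nb)
    list(ds = subj_ds, sex = subj_sex, edu = subj_edu, apoe = subj_apoe,
         age0 = subj_age0, b0 = b0, b1 = b1, eps = eps)
  })

  subj_idx <- rep(seq_len(ns), each = nv)
  visit <- rep(seq_len(nv), ns)
  age <- dat$age0[subj_idx] + (visit - 1)
  cov_df <- data.frame(age = age,
                       ds = dat$ds[subj_idx],
                       sex = dat$sex[subj_idx],
                       education = dat$edu[subj_idx],
                       apoe4 = dat$apoe[subj_idx])
  X <- build_design(cov_df)
  fixed <- X %*% t(beta)                      # (ns*nv) x nb
  values <- fixed + dat$b0[subj_idx, , drop = FALSE] +
    dat$b1[subj_idx, , drop = FALSE] * age + dat$eps

  subject_id <- sprintf("S%04d", seq_len(ns))
  cohort <- data.frame(
    subject_id = rep(subject_id[subj_idx], each = nb),
    visit = rep(visit, each = nb),
    age = rep(age, each = nb),
    sex = rep(cov_df$sex, each = nb),
    education = rep(cov_df$education, each = nb),
    apoe4 = rep(cov_df$apoe4, each = nb),
    ds = rep(cov_df$ds, each = nb),
    biomarker_id = rep(ids, ns * nv),
    value = as.vector(t(values)),
    stringsAsFactors = FALSE)

  meta <- parse_biomarker_ids(ids, config$factor_names)
  fac_mag <- vapply(config$factor_names, function(f) {
    mean(abs(beta[meta$biomarker_id[meta$imaging & meta$factor == f], "ds"]))
  }, numeric(1))
  truth <- structure(list(
    planted_factor_order = names(sort(fac_mag, decreasing = TRUE)),
    converter_ids = character(0),
    outlier_records = data.frame(subject_id = character(0),
                                 visit = integer(0),
                                 biomarker_id = character(0),
                                 shift = numeric(0),
                                 stringsAsFactors = FALSE),
    beta_true = beta,
    random_effect_sd = config$random_effect_sd,
    noise_sd = config$noise_sd), class = "ground_truth")

  out <- list(cohort = cohort, truth = truth)
  if (config$converter_fraction > 0)
    out <- plant_converters(out$cohort, out$truth, config$converter_fraction,
                            seed = stream_seed(config$seed, "converters"))
  if (config$outlier_fraction > 0)
    out <- plant_outliers(out$cohort, out$truth, config$outlier_fraction,
                          config$outlier_magnitude,
                          seed = stream_seed(config$seed, "outliers"))
  out
}

#' Plant clinical converters into a cohort
#'
#' Turns a fraction of subjects (rounded down) into clinical converters: their
#' diagnosis code `ds` increases strictly at a randomly chosen later visit and
#' stays at the new value afterwards. These are the cases the first quality
#' control step must remove.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#' @param truth the accompanying `ground_truth` object.
#' @param fraction fraction of subjects to convert, in [0, 1).
#' @param seed integer seed for the converter stream.
#' @return list(cohort, truth) with converted subjects and their ids appended
#'   to `truth$converter_ids`.
#' @export
plant_converters <- function(cohort, truth, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  n_convert <- floor(length(unique(cohort$subject_id)) * fraction)
  if (n_convert == 0) return(list(cohort = cohort, truth = truth))

  sub_info <- unique(cohort[, c("subject_id", "visit", "ds")])
  by_sub <- split(sub_info, sub_info$subject_id)
  eligible <- names(by_sub)[vapply(by_sub, function(d)
    nrow(d) >= 2 && min(d$ds) < 4, logical(1))]
  if (length(eligible) < n_convert)
    stop("not enough eligible subjects (need ds < 4 and >= 2 visits) to plant ",
         n_convert, " converters")

  with_seed(seed, {
    chosen <- sample(eligible, n_convert)
    for (sid in chosen) {
      visits <- sort(by_sub[[sid]]$visit)
      change_at <- if (length(visits) == 2) visits[2] else
        sample(visits[-1], 1)
      old_ds <- by_sub[[sid]]$ds[1]
      new_ds <- if (old_ds + 1 == 4) 4L else sample(seq(old_ds + 1, 4), 1)
      sel <- cohort$subject_id == sid & cohort$visit >= change_at
      cohort$ds[sel] <- new_ds
    }
    truth$converter_ids <- c(truth$converter_ids, chosen)
  })
  list(cohort = cohort, truth = truth)
}

#' Plant gross outlier records into a cohort
#'
#' Shifts a fraction of subject-visit-biomarker records by a fixed multiple of
#' the within-clinical-group standard deviation of that biomarker (computed on
#' the clean cohort before any shift). These are the cases the Mahalanobis
#' outlier detection step must flag.
#'
#' @inheritParams plant_converters
#' @param fraction fraction of records to corrupt, in [0, 1).
#' @param magnitude shift size in within-group sd units (> 0).
#' @param seed integer seed for the outlier stream.
#' @return list(cohort, truth) with shifted values and the affected records
#'   appended to `truth$outlier_records`.
#' @export
plant_outliers <- function(cohort, truth, fraction, magnitude, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  if (magnitude <= 0) stop("magnitude must be > 0")
  n_out <- floor(nrow(cohort) * fraction)
  if (n_out == 0) return(list(cohort = cohort, truth = truth))

  grp <- interaction(cohort$biomarker_id, cohort$ds, drop = TRUE)
  grp_sd <- tapply(cohort$value, grp, stats::sd)
  grp_sd[is.na(grp_sd)] <- 0

  with_seed(seed, {
    rows <- sample(nrow(cohort), n_out)
    shift <- magnitude * grp_sd[as.character(grp[rows])]
    cohort$value[rows] <- cohort$value[rows] + shift
    truth$outlier_records <- rbind(
      truth$outlier_records,
      data.frame(subject_id = cohort$subject_id[rows],
                 visit = cohort$visit[rows],
                 biomarker_id = cohort$biomarker_id[rows],
                 shift = unname(shift),
                 stringsAsFactors = FALSE))
  })
  list(cohort = cohort, truth = truth)
}

#' Validate a cohort table
#'
#' Checks the tidy cohort schema: required columns, numeric types, uniqueness
#' of (subject_id, visit, biomarker_id), strictly increasing age within
#' subject, diagnosis defined at every visit, and coded covariate ranges.
#'
#' @param cohort a data.frame.
#' @return the cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- c("visit", "age", "sex", "education", "apoe4", "ds", "value")
  for (cl in num_cols) {
    if (!is.numeric(cohort[[cl]]))
      stop("cohort column '", cl, "' must be numeric")
  }
  if (anyNA(cohort$ds)) stop("ds must be defined at every visit")
  if (!all(cohort$ds %in% 1:4)) stop("ds must take values in 1..4")
  if (!all(cohort$sex %in% 0:1)) stop("sex must be coded 0/1")
  if (!all(cohort$apoe4 %in% 0:2)) stop("apoe4 must be an allele count 0/1/2")
  key <- paste(cohort$subject_id, cohort$visit, cohort$biomarker_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject_id, visit, biomarker_id) records found")
  sv <- unique(cohort[, c("subject_id", "visit", "age")])
  sv <- sv[order(sv$subject_id, sv$visit), ]
  bad <- unlist(lapply(split(sv$age, sv$subject_id),
                       function(a) any(diff(a) <= 0)))
  if (any(bad))
    stop("age must be strictly increasing across visits for subject(s): ",
         paste(names(bad)[bad], collapse = ", "))
  invisible(cohort)
}
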