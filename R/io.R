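# Readers/writers and the reproducible end-to-end run: every table is plain
# delimited text with a fixed, documented header; the fully resolved
# configuration is echoed into the results directory alongside a run log.

#' Read a cohort table from delimited text
#'
#' Expects the tidy schema subject_id, visit, age, sex, education, apoe4, ds,
#' biomarker_id, value. Rows are validated ([validate_cohort()]); malformed
#' input produces descriptive errors.
#'
#' @param path file path.
#' @param sep field separator (default comma; use "\t" for TSV).
#' @return validated cohort data.frame.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("cohort file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cl in c("visit", "age", "sex", "education", "apoe4", "ds", "value")) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))) &
                     !is.na(df[[cl]]))
      stop("non-numeric value(s) in column '", cl, "' at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  df <- df[, COHORT_COLUMNS]
  validate_cohort(df)
  df
}

#' Write a cohort table as CSV
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, COHORT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Write / read the ground-truth sidecar of a synthetic cohort
#'
#' Ground truth (planted factor order, converter ids, outlier records, true
#' coefficients) is stored as JSON next to the cohort so downstream checks
#' can recover it.
#'
#' @param truth a `ground_truth` object.
#' @param path output path (JSON).
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(planted_factor_order = truth$planted_factor_order,
                  converter_ids = truth$converter_ids,
                  outlier_records = truth$outlier_records,
                  beta_true = list(rownames = rownames(truth$beta_true),
                                   colnames = colnames(truth$beta_true),
                                   values = unname(truth$beta_true)),
                  random_effect_sd = truth$random_effect_sd,
                  noise_sd = truth$noise_sd)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- as.matrix(p$beta_true$values)
  dimnames(beta) <- list(p$beta_true$rownames, p$beta_true$colnames)
  structure(list(planted_factor_order = p$planted_factor_order,
                 converter_ids = as.character(p$converter_ids %||% character(0)),
                 outlier_records = as.data.frame(p$outlier_records),
                 beta_true = beta,
                 random_effect_sd = p$random_effect_sd,
                 noise_sd = p$noise_sd),
            class = "ground_truth")
}

#' Build and validate a run configuration
#'
#' Collects every tunable of the end-to-end run with documented defaults and
#' range checks; the resolved configuration is echoed into the results
#' directory by [run_all()]. Configurations can also be read from YAML with
#' [read_run_config()].
#'
#' @param cohort_path path to an input cohort CSV; NULL to simulate instead.
#' @param results_dir output directory.
#' @param simulate list of [synthetic_config()] arguments used when
#'   `cohort_path` is NULL.
#' @param qc_percentile,qc_alpha,qc_scope quality control parameters.
#' @param variants model variants to try.
#' @param weighting marginalization weighting.
#' @param shape,sigmoid_params disease-state path options.
#' @param n_grid number of age grid points.
#' @param age_range age range of the grid.
#' @param k_scope abnormality-index normalization scope.
#' @param bootstrap_B bootstrap resamples (0 disables the bootstrap stage).
#' @param seed root seed for the whole run.
#' @param factor_names imaging factor names.
#' @return validated `run_config` list.
#' @export
run_config <- function(cohort_path = NULL,
                       results_dir = "results",
                       simulate = list(),
                       qc_percentile = 10,
                       qc_alpha = 0.05,
                       qc_scope = "modality",
                       variants = c("fixed_robust", "mixed_intercept",
                                    "mixed_intercept_slope"),
                       weighting = "uniform",
                       shape = "linear",
                       sigmoid_params = list(midpoint = 55, width = 20),
                       n_grid = 1560,
                       age_range = c(40, 70),
                       k_scope = "all",
                       bootstrap_B = 500,
                       seed = 1L,
                       factor_names = c("vascular", "amyloid", "metabolic",
                                        "functional", "structural")) {
  if (qc_percentile <= 0 || qc_percentile >= 100)
    stop("qc_percentile must lie in (0, 100)")
  if (qc_alpha <= 0 || qc_alpha >= 1) stop("qc_alpha must lie in (0, 1)")
  if (!qc_scope %in% c("modality", "biomarker"))
    stop("qc_scope must be 'modality' or 'biomarker'")
  variants <- match.arg(variants, several.ok = TRUE)
  if (!weighting %in% c("uniform", "empirical"))
    stop("weighting must be 'uniform' or 'empirical'")
  if (!shape %in% c("linear", "sigmoid"))
    stop("shape must be 'linear' or 'sigmoid'")
  if (!is_scalar_number(n_grid) || n_grid < 2)
    stop("n_grid must be an integer >= 2")
  if (!k_scope %in% c("all", "group"))
    stop("k_scope must be 'all' or 'group'")
  if (!is_scalar_number(bootstrap_B) || bootstrap_B < 0 ||
      (bootstrap_B > 0 && bootstrap_B < 2))
    stop("bootstrap_B must be 0 (disabled) or >= 2")
  structure(list(cohort_path = cohort_path, results_dir = results_dir,
                 simulate = simulate, qc_percentile = qc_percentile,
                 qc_alpha = qc_alpha, qc_scope = qc_scope,
                 variants = variants, weighting = weighting, shape = shape,
                 sigmoid_params = sigmoid_params, n_grid = n_grid,
                 age_range = age_range, k_scope = k_scope,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed),
                 factor_names = factor_names),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of configuration fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  fields <- yaml::read_yaml(path)
  do.call(run_config, fields)
}

write_resolved_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis end to end
#'
#' Executes simulate (when no input cohort is given) -> quality control ->
#' standardization -> per-biomarker fitting and BIC selection ->
#' marginalization -> trajectories -> abnormality curves and indices ->
#' ordering -> bootstrap, writing every intermediate table as CSV plus the
#' resolved configuration and a stage-timing log into the results directory.
#' Reruns with the same configuration are bit-identical.
#'
#' @param config a `run_config` object (or path to a YAML config).
#' @return invisibly, a list with the in-memory results
#'   (`cohort`, `qc`, `scaling`, `analysis`, `bootstrap`).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$results_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$results_dir, "run_log.txt")
  cat("run started\n", file = log_path)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    cat(sprintf("%-14s done at %8.2fs\n", name,
                proc.time()[["elapsed"]] - t0),
        file = log_path, append = TRUE)
    res
  }
  write_resolved_config(config,
                        file.path(config$results_dir, "resolved_config.yaml"))

  cohort <- stage("input", {
    if (is.null(config$cohort_path)) {
      sim_args <- utils::modifyList(list(seed = config$seed,
                                         factor_names = config$factor_names),
                                    config$simulate)
      sim <- generate_cohort(do.call(synthetic_config, sim_args))
      write_cohort(sim$cohort, file.path(config$results_dir, "cohort.csv"))
      write_ground_truth(sim$truth,
                         file.path(config$results_dir, "ground_truth.json"))
      sim$cohort
    } else read_cohort(config$cohort_path)
  })

  qc <- stage("qc", run_qc(cohort, percentile = config$qc_percentile,
                           alpha = config$qc_alpha, scope = config$qc_scope,
                           factor_names = config$factor_names))
  utils::write.csv(qc$report$sizes,
                   file.path(config$results_dir, "qc_sizes.csv"),
                   row.names = FALSE)
  utils::write.csv(qc$report$outliers$outlier_flags,
                   file.path(config$results_dir, "qc_outlier_flags.csv"),
                   row.names = FALSE)
  writeLines(c("quality control report",
               paste("step (i)  converters removed:",
                     length(qc$report$converters$removed_converters)),
               paste("step (ii) low-likelihood removed:",
                     length(qc$report$likelihood$removed_low_likelihood)),
               paste("step (iii) outlier records flagged:",
                     nrow(qc$report$outliers$outlier_flags))),
             file.path(config$results_dir, "qc_report.txt"))

  std <- stage("standardize", standardize_biomarkers(qc$cohort))
  write_cohort(std$cohort,
               file.path(config$results_dir, "cohort_standardized.csv"))
  utils::write.csv(std$scaling,
                   file.path(config$results_dir, "standardization.csv"),
                   row.names = FALSE)

  grid <- age_grid(config$n_grid, config$age_range)
  analysis <- stage("analysis",
                    progression_analysis(std$cohort,
                                         variants = config$variants,
                                         weighting = config$weighting,
                                         shape = config$shape,
                                         grid = grid,
                                         sigmoid_params = config$sigmoid_params,
                                         factor_names = config$factor_names,
                                         k_scope = config$k_scope))
  utils::write.csv(fits_table(analysis$fits),
                   file.path(config$results_dir, "model_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$trajectories,
                   file.path(config$results_dir, "trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$curves,
                   file.path(config$results_dir, "abnormality_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$index_table,
                   file.path(config$results_dir, "abnormality_indices.csv"),
                   row.names = FALSE)
  if (!is.null(analysis$hierarchy)) {
    utils::write.csv(as.data.frame(analysis$hierarchy$H),
                     file.path(config$results_dir, "hierarchical_matrix.csv"))
    utils::write.csv(analysis$vulnerability,
                     file.path(config$results_dir,
                               "regional_vulnerability.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$factor_curves,
                     file.path(config$results_dir, "factor_curves.csv"),
                     row.names = FALSE)
    writeLines(analysis$ranking,
               file.path(config$results_dir, "ranking.txt"))
  }

  boot <- NULL
  if (config$bootstrap_B > 0) {
    boot <- stage("bootstrap",
                  bootstrap_pipeline(std$cohort, B = config$bootstrap_B,
                                     seed = config$seed,
                                     variants = config$variants,
                                     weighting = config$weighting,
                                     shape = config$shape, grid = grid,
                                     sigmoid_params = config$sigmoid_params,
                                     factor_names = config$factor_names,
                                     k_scope = config$k_scope))
    for (nm in names(boot$summaries)) {
      utils::write.csv(boot$summaries[[nm]],
                       file.path(config$results_dir,
                                 paste0("bootstrap_", nm, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(boot$ranking_table))
      utils::write.csv(boot$ranking_table,
                       file.path(config$results_dir,
                                 "bootstrap_rankings.csv"),
                       row.names = FALSE)
  }
  cat("run completed\n", file = log_path, append = TRUE)
  invisible(list(cohort = cohort, qc = qc, scaling = std$scaling,
                 analysis = analysis, bootstrap = boot))
}
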