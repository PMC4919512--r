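# Bootstrap engine: the whole post-QC pipeline is re-run on cohorts resampled
# at the subject level (all of a subject's visits travel together, preserving
# the random-effects correlation structure) to yield means and 95% percentile
# confidence bands for trajectories, abnormality curves, indices and the
# hierarchical matrix.

resample_subjects <- function(cohort, seed) {
  ids <- unique(cohort$subject_id)
  rows_by_subject <- split(seq_len(nrow(cohort)), cohort$subject_id)
  drawn <- with_seed(seed, sample(ids, length(ids), replace = TRUE))
  parts <- lapply(seq_along(drawn), function(k) {
    d <- cohort[rows_by_subject[[drawn[k]]], , drop = FALSE]
    # duplicated draws become distinct subjects so mixed-model grouping and
    # uniqueness invariants stay valid
    d$subject_id <- sprintf("%s#%03d", drawn[k], k)
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

band_summary <- function(mat, ids) {
  cbind(ids,
        data.frame(mean = rowMeans(mat),
                   lower = apply(mat, 1, stats::quantile, 0.025, names = FALSE),
                   upper = apply(mat, 1, stats::quantile, 0.975,
                                 names = FALSE)))
}

#' Bootstrap the progression pipeline
#'
#' Draws `B` resampled cohorts (subjects with replacement), reruns
#' [progression_analysis()] on each, and summarizes every tracked quantity by
#' its replicate mean and 2.5/97.5 percentile band. Reported point estimates
#' are the replicate means. Replicates whose fit fails are logged and
#' skipped; more than `max_failure_rate` failures abort the run.
#'
#' @inheritParams progression_analysis
#' @param B number of bootstrap resamples (default 500).
#' @param seed integer root seed; per-replicate seeds are derived by counter
#'   so replicates are individually reproducible.
#' @param keep which quantities to track across replicates; tracking
#'   per-biomarker `"trajectories"`/`"abnormality"` stores a grid x B matrix
#'   per quantity, which is memory-heavy for large biomarker sets.
#' @param max_failure_rate run-level error threshold on the failed-replicate
#'   fraction.
#' @param ... passed to [progression_analysis()].
#' @return object of class `bootstrap_result`: summaries (`trajectories`,
#'   `abnormality`, `indices`, `hierarchy`, `factor_curves` — long
#'   data.frames with mean/lower/upper), `ranking_table` (frequency of each
#'   recovered factor order), `n_resamples`, `n_success`, `failures`, `seed`.
#' @export
bootstrap_pipeline <- function(cohort, B = 500, seed = 1L,
                               keep = c("indices", "hierarchy",
                                        "factor_curves", "trajectories",
                                        "abnormality"),
                               max_failure_rate = 0.2, ...) {
  if (B < 2) stop("B must be >= 2")
  keep <- match.arg(keep, several.ok = TRUE)
  validate_cohort(cohort)
  domains <- covariate_domains(cohort)
  root <- stream_seed(seed, "bootstrap")

  acc <- list()
  template <- NULL
  failures <- data.frame(replicate = integer(0), message = character(0),
                         stringsAsFactors = FALSE)
  rankings <- character(0)

  for (b in seq_len(B)) {
    res <- tryCatch({
      rep_cohort <- resample_subjects(cohort, seed = (root + b) %% (2^31 - 1))
      progression_analysis(rep_cohort, domains = domains, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(replicate = b,
                                   message = conditionMessage(res),
                                   stringsAsFactors = FALSE))
      next
    }
    vecs <- list()
    if ("trajectories" %in% keep) vecs$trajectories <- res$trajectories$value
    if ("abnormality" %in% keep) vecs$abnormality <- res$curves$value
    if ("indices" %in% keep)
      vecs$indices <- c(res$index_table$total_index,
                        res$index_table$emci_index,
                        res$index_table$lmci_index)
    if ("hierarchy" %in% keep && !is.null(res$hierarchy)) {
      fac <- sort(res$hierarchy$ordering)
      vecs$hierarchy <- as.vector(res$hierarchy$H[fac, fac])
    }
    if ("factor_curves" %in% keep && !is.null(res$factor_curves)) {
      fc <- res$factor_curves[order(res$factor_curves$curve_id,
                                    res$factor_curves$age), , drop = FALSE]
      vecs$factor_curves <- fc$value
    }
    if (!is.null(res$factor_ranking))
      rankings <- c(rankings, paste(res$factor_ranking, collapse = " > "))
    if (is.null(template)) template <- res
    acc[[length(acc) + 1L]] <- vecs
  }

  n_success <- length(acc)
  if (n_success < (1 - max_failure_rate) * B)
    stop("bootstrap failed in ", B - n_success, " of ", B,
         " replicates (threshold ", max_failure_rate * 100, "%); first error: ",
         failures$message[1])

  summaries <- list()
  get_mat <- function(name)
    do.call(cbind, lapply(acc, function(v) v[[name]]))
  if ("trajectories" %in% keep) {
    ids <- template$trajectories[, c("biomarker_id", "transition", "age", "ds")]
    summaries$trajectories <- band_summary(get_mat("trajectories"), ids)
  }
  if ("abnormality" %in% keep) {
    ids <- template$curves[, c("biomarker_id", "transition", "age")]
    summaries$abnormality <- band_summary(get_mat("abnormality"), ids)
  }
  if ("indices" %in% keep) {
    nb <- nrow(template$index_table)
    ids <- data.frame(biomarker_id = rep(template$index_table$biomarker_id, 3),
                      measure = rep(c("total", "emci", "lmci"), each = nb),
                      stringsAsFactors = FALSE)
    summaries$indices <- band_summary(get_mat("indices"), ids)
  }
  if ("hierarchy" %in% keep && !is.null(template$hierarchy)) {
    fac <- sort(template$hierarchy$ordering)
    ids <- expand.grid(factor_i = fac, factor_j = fac,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    summaries$hierarchy <- band_summary(get_mat("hierarchy"), ids)
  }
  if ("factor_curves" %in% keep && !is.null(template$factor_curves)) {
    fc <- template$factor_curves[order(template$factor_curves$curve_id,
                                       template$factor_curves$age), ,
                                 drop = FALSE]
    summaries$factor_curves <- band_summary(get_mat("factor_curves"),
                                            fc[, c("curve_id", "age")])
  }
  ranking_table <- if (length(rankings))
    as.data.frame(sort(table(ranking = rankings), decreasing = TRUE),
                  stringsAsFactors = FALSE)
  else NULL

  structure(list(summaries = summaries,
                 ranking_table = ranking_table,
                 n_resamples = B,
                 n_success = n_success,
                 failures = failures,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result>", x$n_success, "of", x$n_resamples,
      "replicates succeeded (seed", paste0(x$seed, ")\n"))
  if (!is.null(x$ranking_table)) {
    cat("recovered factor orderings:\n")
    print(utils::head(x$ranking_table, 3))
  }
  invisible(x)
}
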