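# Three-step cohort homogeneity / quality control:
#   (i)  remove clinical converters,
#   (ii) remove subjects atypical of their assigned diagnosis
#        (leave-one-subject-out Gaussian class likelihood, lowest decile),
#   (iii) remove biomarker records flagged as multivariate Mahalanobis
#        outliers within their clinical group.

# Group mean/covariance with a shrinkage fallback: the plain sample covariance
# is used whenever it is comfortably identifiable (n >= d + 2 and numerically
# invertible); otherwise a Ledoit-Wolf-style scaled-identity shrinkage is used.
group_gaussian <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  mu <- colMeans(x)
  use_plain <- n >= d + 2
  if (use_plain) {
    sigma <- stats::cov(x)
    ok <- tryCatch({
      solve(sigma)
      is.finite(determinant(sigma)$modulus)
    }, error = function(e) FALSE)
    if (ok) return(list(mu = mu, sigma = sigma, shrunk = FALSE))
  }
  sc <- shrink_cov(x)
  list(mu = mu, sigma = sc$sigma, shrunk = TRUE)
}

# Per-subject multimodal feature vectors: region-averaged value per imaging
# factor plus each scalar biomarker, averaged over visits. Returns a list with
# the feature matrix (rownames = subject ids) and the per-subject diagnosis.
subject_features <- function(cohort, factor_names) {
  meta <- parse_biomarker_ids(unique(cohort$biomarker_id), factor_names)
  cohort$feature <- with(meta[match(cohort$biomarker_id, meta$biomarker_id), ],
                         ifelse(imaging, factor, biomarker_id))
  agg <- stats::aggregate(value ~ subject_id + feature, cohort, mean)
  feats <- sort(unique(agg$feature))
  m <- matrix(NA_real_, nrow = length(unique(agg$subject_id)),
              ncol = length(feats),
              dimnames = list(sort(unique(agg$subject_id)), feats))
  m[cbind(agg$subject_id, agg$feature)] <- agg$value
  ds <- tapply(cohort$ds, cohort$subject_id, function(x) x[1])
  list(features = m, ds = ds[rownames(m)])
}

#' Remove clinical converters (QC step one)
#'
#' Removes entirely every subject whose diagnosis code changes across visits;
#' subjects with a stable diagnosis are untouched.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#' @return list with `cohort` (retained records) and `report` (a `qc_report`
#'   with the removed subject ids and cohort sizes before/after).
#' @export
remove_converters <- function(cohort) {
  n_distinct_ds <- tapply(cohort$ds, cohort$subject_id,
                          function(x) length(unique(x)))
  converters <- names(n_distinct_ds)[n_distinct_ds > 1]
  kept <- cohort[!(cohort$subject_id %in% converters), , drop = FALSE]
  report <- structure(list(step = "remove_converters",
                           removed_converters = converters,
                           n_subjects_before = length(n_distinct_ds),
                           n_subjects_after = length(n_distinct_ds) -
                             length(converters)),
                      class = "qc_report")
  list(cohort = kept, report = report)
}

#' Diagnosis-likelihood scores (QC step two, scoring)
#'
#' Scores how typical each subject's multimodal feature vector (region-averaged
#' value per imaging factor plus scalar biomarkers, averaged over visits) is of
#' its assigned clinical group. The score is the leave-one-subject-out Gaussian
#' class-conditional log-likelihood, rank-normalized within the group to
#' (0, 1]; higher means more typical of the diagnosis.
#'
#' @inheritParams remove_converters
#' @param factor_names imaging factor names used to parse biomarker ids.
#' @return named numeric vector of scores in (0, 1], one per subject.
#' @export
diagnosis_likelihood_scores <- function(cohort,
                                        factor_names = c("vascular", "amyloid",
                                                         "metabolic",
                                                         "functional",
                                                         "structural")) {
  sf <- subject_features(cohort, factor_names)
  feats <- sf$features
  if (anyNA(feats)) stop("incomplete feature vectors; all subjects need every ",
                         "imaging factor and scalar biomarker")
  d <- ncol(feats)
  scores <- stats::setNames(numeric(nrow(feats)), rownames(feats))
  for (g in sort(unique(sf$ds))) {
    idx <- which(sf$ds == g)
    ng <- length(idx)
    if (ng < d + 2)
      stop("clinical group DS=", g, " has only ", ng,
           " subjects; need more subjects than the feature dimension (", d,
           ") to estimate its covariance")
    ll <- numeric(ng)
    for (k in seq_len(ng)) {
      rest <- feats[idx[-k], , drop = FALSE]
      gg <- group_gaussian(rest)
      d2 <- stats::mahalanobis(feats[idx[k], , drop = FALSE], gg$mu, gg$sigma)
      ld <- as.numeric(determinant(gg$sigma, logarithm = TRUE)$modulus)
      ll[k] <- -0.5 * (d * log(2 * pi) + ld + d2)
    }
    scores[idx] <- rank(ll, ties.method = "average") / ng
  }
  scores
}

#' Filter subjects with low diagnosis-likelihood scores (QC step two, filter)
#'
#' Removes, within each clinical group, the subjects whose score falls strictly
#' below the given within-group percentile (default the 10th). The strictly-
#' below rule means all-tied scores remove nobody.
#'
#' @inheritParams remove_converters
#' @param scores named scores from [diagnosis_likelihood_scores()].
#' @param percentile cut percentile in (0, 100).
#' @return list with the filtered `cohort` and a `qc_report`.
#' @export
filter_low_likelihood <- function(cohort, scores, percentile = 10) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  subjects <- unique(cohort$subject_id)
  missing <- setdiff(subjects, names(scores))
  if (length(missing))
    stop("scores missing for subject(s): ", paste(missing, collapse = ", "))
  ds <- tapply(cohort$ds, cohort$subject_id, function(x) x[1])[subjects]
  removed <- character(0)
  for (g in sort(unique(ds))) {
    ids <- subjects[ds == g]
    s <- scores[ids]
    # type 6 keeps the p -> 0 limit removal-free while matching the
    # expected count at the decile on untied scores
    cut <- stats::quantile(s, percentile / 100, names = FALSE, type = 6)
    removed <- c(removed, ids[s < cut])
  }
  kept <- cohort[!(cohort$subject_id %in% removed), , drop = FALSE]
  report <- structure(list(step = "filter_low_likelihood",
                           likelihood_scores = scores,
                           removed_low_likelihood = removed,
                           percentile = percentile,
                           n_subjects_before = length(subjects),
                           n_subjects_after = length(subjects) - length(removed)),
                      class = "qc_report")
  list(cohort = kept, report = report)
}

#' Mahalanobis outlier detection (QC step three)
#'
#' Flags, within each clinical group, records whose squared Mahalanobis
#' distance exceeds the chi-square `1 - alpha` quantile, and removes the
#' offending biomarker values (not the whole subject). Under
#' `scope = "modality"` the imaging biomarkers of each factor are treated as
#' one multivariate feature vector across all regions (d = number of regions);
#' scalar biomarkers are always tested univariately. Under
#' `scope = "biomarker"` every biomarker is tested univariately. When a group
#' is too small for a plain covariance estimate a Ledoit-Wolf-style shrinkage
#' covariance is used; the chi-square reference keeps the full feature count.
#'
#' @inheritParams diagnosis_likelihood_scores
#' @param alpha significance level in (0, 1); default 0.05.
#' @param scope `"modality"` (multivariate across regions, the default) or
#'   `"biomarker"` (univariate per biomarker).
#' @return list with the filtered `cohort` and a `qc_report` whose
#'   `outlier_flags` table holds (subject_id, visit, unit, squared_distance,
#'   p_value) for every flagged record.
#' @export
detect_outliers_mahalanobis <- function(cohort, alpha = 0.05,
                                        scope = c("modality", "biomarker"),
                                        factor_names = c("vascular", "amyloid",
                                                         "metabolic",
                                                         "functional",
                                                         "structural")) {
  scope <- match.arg(scope)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  meta <- parse_biomarker_ids(unique(cohort$biomarker_id), factor_names)
  bm_meta <- meta[match(cohort$biomarker_id, meta$biomarker_id), ]
  unit <- if (scope == "modality")
    ifelse(bm_meta$imaging, bm_meta$factor, cohort$biomarker_id)
  else cohort$biomarker_id

  flags <- list()
  drop_rows <- logical(nrow(cohort))
  for (g in sort(unique(cohort$ds))) {
    in_group <- cohort$ds == g
    for (u in unique(unit[in_group])) {
      sel <- in_group & unit == u
      sub <- cohort[sel, , drop = FALSE]
      wide <- tapply(sub$value, list(paste(sub$subject_id, sub$visit, sep = "\r"),
                                     sub$biomarker_id), mean)
      wide <- wide[stats::complete.cases(wide), , drop = FALSE]
      n <- nrow(wide)
      d <- ncol(wide)
      if (n < 3) next
      gg <- group_gaussian(wide)
      if (d == 1 && gg$sigma[1, 1] == 0) next
      d2 <- tryCatch(stats::mahalanobis(wide, gg$mu, gg$sigma),
                     error = function(e)
                       stop("singular covariance for group DS=", g, ", unit '",
                            u, "'; shrinkage regularization failed"))
      thr <- stats::qchisq(1 - alpha, df = d)
      hit <- which(d2 > thr)
      if (length(hit)) {
        sv <- do.call(rbind, strsplit(rownames(wide)[hit], "\r", fixed = TRUE))
        flags[[length(flags) + 1L]] <-
          data.frame(subject_id = sv[, 1],
                     visit = as.integer(sv[, 2]),
                     unit = u, ds = g,
                     squared_distance = unname(d2[hit]),
                     p_value = unname(1 - stats::pchisq(d2[hit], df = d)),
                     stringsAsFactors = FALSE)
        key_hit <- rownames(wide)[hit]
        drop_rows <- drop_rows |
          (sel & paste(cohort$subject_id, cohort$visit, sep = "\r") %in% key_hit)
      }
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(subject_id = character(0), visit = integer(0),
               unit = character(0), ds = numeric(0),
               squared_distance = numeric(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  report <- structure(list(step = "detect_outliers_mahalanobis",
                           alpha = alpha, scope = scope,
                           outlier_flags = flags,
                           n_records_before = nrow(cohort),
                           n_records_after = nrow(cohort) - sum(drop_rows)),
                      class = "qc_report")
  list(cohort = cohort[!drop_rows, , drop = FALSE], report = report)
}

#' Run the full three-step quality control
#'
#' Applies, in order: (i) converter removal, (ii) diagnosis-likelihood
#' filtering at the given percentile, (iii) within-group Mahalanobis outlier
#' removal. Each step feeds the next; cohort sizes are monotone non-increasing.
#'
#' @inheritParams detect_outliers_mahalanobis
#' @param percentile within-group likelihood-score cut percentile.
#' @return list with the QC'd `cohort` and `report`, a list of the three step
#'   reports plus a size summary.
#' @export
run_qc <- function(cohort, percentile = 10, alpha = 0.05,
                   scope = c("modality", "biomarker"),
                   factor_names = c("vascular", "amyloid", "metabolic",
                                    "functional", "structural")) {
  scope <- match.arg(scope)
  s1 <- remove_converters(cohort)
  scores <- diagnosis_likelihood_scores(s1$cohort, factor_names)
  s2 <- filter_low_likelihood(s1$cohort, scores, percentile)
  s3 <- detect_outliers_mahalanobis(s2$cohort, alpha, scope, factor_names)
  sizes <- data.frame(
    step = c("input", "remove_converters", "filter_low_likelihood",
             "detect_outliers"),
    n_subjects = c(length(unique(cohort$subject_id)),
                   s1$report$n_subjects_after,
                   s2$report$n_subjects_after,
                   length(unique(s3$cohort$subject_id))),
    n_records = c(nrow(cohort), nrow(s1$cohort), nrow(s2$cohort),
                  nrow(s3$cohort)))
  list(cohort = s3$cohort,
       report = structure(list(converters = s1$report, likelihood = s2$report,
                               outliers = s3$report, sizes = sizes),
                          class = "qc_report"))
}
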