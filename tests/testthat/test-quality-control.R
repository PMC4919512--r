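test_that("converter removal drops exactly the subjects whose ds changes", {
  vals <- matrix(rnorm(12), 4, 3)
  cohort <- rbind(scalar_cohort(vals, ds = c(1, 1, 2, 3)),
                  transform(scalar_cohort(vals, ds = c(1, 1, 2, 3)),
                            visit = 2L, age = 60))
  # subject P002 converts at visit 2
  cohort$ds[cohort$subject_id == "P002" & cohort$visit == 2] <- 2
  out <- remove_converters(cohort)
  expect_identical(out$report$removed_converters, "P002")
  expect_false("P002" %in% out$cohort$subject_id)

  stable <- remove_converters(out$cohort)
  expect_identical(stable$cohort, out$cohort)
})

test_that("converter removal matches a per-subject scan oracle on planted data", {
  sim <- generate_cohort(tiny_config(n_subjects = 10, noise_sd = 0.5,
                                     group_proportions = c(1, 0, 0, 0),
                                     seed = 3))
  planted <- plant_converters(sim$cohort, sim$truth, 0.3, seed = 8)
  oracle <- vapply(split(planted$cohort$ds, planted$cohort$subject_id),
                   function(x) length(unique(x)) > 1, logical(1))
  out <- remove_converters(planted$cohort)
  expect_setequal(out$report$removed_converters, names(oracle)[oracle])
  expect_setequal(out$report$removed_converters, planted$truth$converter_ids)
  expect_equal(length(unique(out$cohort$subject_id)), 7)
})

test_that("likelihood scores peak at the group centroid and respect symmetry", {
  vals <- matrix(c(-3, -2, -1, 0, 1, 2, 3, 0), ncol = 1)
  cohort <- scalar_cohort(vals, ds = rep(1, 8))
  scores <- diagnosis_likelihood_scores(cohort, factor_names = character(0))
  # subjects 4 and 8 sit exactly at the centroid: tied maximal score
  expect_equal(unname(scores[c("P004", "P008")]),
               rep(max(scores), 2))
  expect_equal(scores[["P004"]], scores[["P008"]])
  expect_true(all(scores > 0 & scores <= 1))
})

test_that("a displaced subject scores below its group's 10th percentile", {
  set.seed(7)
  n <- 200
  vals <- matrix(rnorm(n * 5), n, 5)
  vals[1, ] <- vals[1, ] + 8
  cohort <- scalar_cohort(vals, ds = rep(1, n))
  scores <- diagnosis_likelihood_scores(cohort, factor_names = character(0))
  expect_equal(scores[["P001"]], min(scores))
  expect_lt(scores[["P001"]], quantile(scores, 0.10))
})

test_that("likelihood filtering removes the lowest decile per group, keeping ties", {
  set.seed(1)
  vals <- matrix(rnorm(200), 200, 1)
  cohort <- scalar_cohort(vals, ds = rep(c(1, 2), each = 100))
  subjects <- unique(cohort$subject_id)
  scores <- setNames(rep(seq_len(100) / 100, 2), subjects)
  out <- filter_low_likelihood(cohort, scores, percentile = 10)
  expect_length(out$report$removed_low_likelihood, 20)  # 10 per group
  tiny <- filter_low_likelihood(cohort, scores, percentile = 1e-6)
  expect_length(tiny$report$removed_low_likelihood, 0)

  tied <- setNames(rep(0.5, 200), subjects)
  out_tied <- filter_low_likelihood(cohort, tied, percentile = 10)
  expect_length(out_tied$report$removed_low_likelihood, 0)

  expect_error(filter_low_likelihood(cohort, scores[-1], percentile = 10),
               subjects[1])
})

test_that("mahalanobis detection flags planted outliers but not the group mean", {
  set.seed(12)
  n <- 500
  vals <- matrix(rnorm(n * 5), n, 5)
  vals[n, ] <- colMeans(vals[-n, ])  # last subject at the (near) centre
  vals[1, 1] <- vals[1, 1] + 10 * sd(vals[-1, 1])
  cohort <- scalar_cohort(vals, ds = rep(1, n),
                          biomarkers = paste0("img.", 1:5))
  out <- detect_outliers_mahalanobis(cohort, alpha = 0.05, scope = "modality",
                                     factor_names = "img")
  flags <- out$report$outlier_flags
  expect_true("P001" %in% flags$subject_id)
  expect_false(sprintf("P%03d", n) %in% flags$subject_id)
  expect_true(all(flags$p_value >= 0 & flags$p_value <= 1))
  expect_true(all(flags$squared_distance >= 0))
  # flagged biomarker values deleted, others retained
  expect_equal(nrow(out$cohort), nrow(cohort) - 5 * nrow(flags))
})

test_that("mahalanobis type-I rate on clean gaussian groups is near alpha", {
  rates <- vapply(1:4, function(s) {
    set.seed(100 + s)
    vals <- matrix(rnorm(1000 * 5), 1000, 5)
    cohort <- scalar_cohort(vals, ds = rep(1, 1000),
                            biomarkers = paste0("img.", 1:5))
    out <- detect_outliers_mahalanobis(cohort, alpha = 0.05,
                                       scope = "modality",
                                       factor_names = "img")
    nrow(out$report$outlier_flags) / 1000
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("flagging is invariant to affine rescaling of one biomarker", {
  set.seed(5)
  vals <- matrix(rnorm(300 * 4), 300, 4)
  cohort <- scalar_cohort(vals, ds = rep(1, 300),
                          biomarkers = paste0("img.", 1:4))
  base <- detect_outliers_mahalanobis(cohort, scope = "modality",
                                      factor_names = "img")
  rescaled <- cohort
  sel <- rescaled$biomarker_id == "img.2"
  rescaled$value[sel] <- 1000 * rescaled$value[sel] - 7
  resc <- detect_outliers_mahalanobis(rescaled, scope = "modality",
                                      factor_names = "img")
  expect_identical(base$report$outlier_flags[, c("subject_id", "visit")],
                   resc$report$outlier_flags[, c("subject_id", "visit")])
  expect_equal(base$report$outlier_flags$squared_distance,
               resc$report$outlier_flags$squared_distance, tolerance = 1e-6)
})

test_that("the qc pipeline is ordered and monotone in cohort size", {
  sim <- generate_cohort(tiny_config(
    n_subjects = 120, n_visits = 3, noise_sd = 1,
    random_effect_sd = c(0.3, 0), seed = 14,
    converter_fraction = 0.1, outlier_fraction = 0.03,
    outlier_magnitude = 8))
  out <- run_qc(sim$cohort, factor_names = "vascular")
  sizes <- out$report$sizes
  expect_true(all(diff(sizes$n_subjects) <= 0))
  expect_true(all(diff(sizes$n_records) <= 0))
  expect_setequal(out$report$converters$removed_converters,
                  sim$truth$converter_ids)
  # planted 8-sd outliers whose subjects survived steps (i)-(ii) should
  # mostly be flagged by step (iii)
  survivors <- setdiff(unique(sim$cohort$subject_id),
                       c(out$report$converters$removed_converters,
                         out$report$likelihood$removed_low_likelihood))
  planted <- sim$truth$outlier_records
  planted <- planted[planted$subject_id %in% survivors, , drop = FALSE]
  expect_gt(nrow(planted), 0)
  flagged <- paste(out$report$outliers$outlier_flags$subject_id,
                   out$report$outliers$outlier_flags$visit)
  expect_gt(mean(paste(planted$subject_id, planted$visit) %in% flagged), 0.8)
})

test_that("groups too small for a covariance produce a named error", {
  vals <- matrix(rnorm(11 * 4), 11, 4)
  cohort <- scalar_cohort(vals, ds = c(rep(1, 7), rep(2, 4)))
  expect_error(diagnosis_likelihood_scores(cohort, factor_names = character(0)),
               "DS=2")
})
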