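test_that("standardization centres and scales with the sample sd", {
  cohort <- scalar_cohort(matrix(c(1, 2, 3), 3, 1))
  out <- standardize_biomarkers(cohort)
  expect_equal(out$cohort$value, c(-1, 0, 1))
  expect_equal(out$scaling$mean, 2)
  expect_equal(out$scaling$sd, 1)

  again <- standardize_biomarkers(out$cohort)
  expect_equal(again$cohort$value, out$cohort$value, tolerance = 1e-12)

  const <- scalar_cohort(cbind(c(1, 2, 3), c(5, 5, 5)))
  expect_warning(res <- standardize_biomarkers(const), "b02")
  expect_false("b02" %in% res$cohort$biomarker_id)
  expect_equal(nrow(res$cohort), 3)
})

test_that("the design matrix has the 16 stated columns in fixed order", {
  d <- data.frame(age = c(50, 60), ds = c(1, 4), sex = c(0, 1),
                  education = c(12, 16), apoe4 = c(0, 2))
  X <- build_design(d)
  expect_equal(ncol(X), 16)
  expect_equal(sum(grepl(":", colnames(X))), 10)
  expect_equal(X[, "age:ds"], X[, "age"] * X[, "ds"])
  expect_equal(X[, "education:apoe4"], X[, "education"] * X[, "apoe4"])

  zeros <- data.frame(age = 0, ds = 0, sex = 0, education = 0, apoe4 = 0)
  Xz <- build_design(zeros)
  expect_equal(unname(Xz[1, ]), c(1, rep(0, 15)))

  expect_error(build_design(d[, -2]), "ds")
})

test_that("the robust fit recovers exact linear data and resists gross outliers", {
  set.seed(31)
  n <- 500
  d <- data.frame(age = runif(n, 40, 70), ds = sample(1:4, n, TRUE),
                  sex = rbinom(n, 1, 0.5), education = sample(6:20, n, TRUE),
                  apoe4 = sample(0:2, n, TRUE))
  X <- build_design(d)
  beta <- setNames(rnorm(16, 0, 0.1), colnames(X))
  y0 <- drop(X %*% beta)
  exact <- fit_fixed_robust(X, y0)
  expect_lt(max(abs(exact$beta - beta)), 1e-8)

  y <- y0 + rnorm(n, 0, 1)
  clean_fit <- fit_fixed_robust(X, y)
  err_clean <- sqrt(sum((clean_fit$beta - beta)^2))

  y_out <- y
  bad <- sample(n, 25)                    # 5% gross outliers at 20 sd
  y_out[bad] <- y_out[bad] + 20
  rob <- fit_fixed_robust(X, y_out)
  ols <- qr.solve(X, y_out)
  err_rob <- sqrt(sum((rob$beta - beta)^2))
  err_ols <- sqrt(sum((ols - beta)^2))
  expect_lt(err_rob, 3 * err_clean)
  expect_gt(err_ols, 3 * err_rob)

  dup <- fit_fixed_robust(rbind(X, X), c(y, y))
  expect_equal(unname(dup$beta), unname(fit_fixed_robust(X, y)$beta),
               tolerance = 1e-8)
})

test_that("rank-deficient designs raise an error listing collinear columns", {
  set.seed(2)
  n <- 100
  d <- data.frame(age = runif(n, 40, 70), ds = sample(1:4, n, TRUE),
                  sex = rbinom(n, 1, 0.5), education = sample(6:20, n, TRUE),
                  apoe4 = sample(0:2, n, TRUE))
  X <- build_design(d)
  X[, "education"] <- X[, "age"]   # force collinearity
  expect_error(fit_fixed_robust(X, rnorm(n)), "collinear")
})

test_that("robust fit without outliers matches least squares closely", {
  set.seed(8)
  n <- 400
  d <- data.frame(age = runif(n, 40, 70), ds = sample(1:4, n, TRUE),
                  sex = rbinom(n, 1, 0.5), education = sample(6:20, n, TRUE),
                  apoe4 = sample(0:2, n, TRUE))
  X <- build_design(d)
  y <- drop(X %*% rnorm(16, 0, 0.1)) + rnorm(n)
  rob <- fit_fixed_robust(X, y)$beta
  ols <- qr.solve(X, y)
  # bisquare downweights mild tails, so compare the fitted surfaces rather
  # than individual (collinearity-inflated) coefficients
  expect_lt(sqrt(mean((X %*% (rob - ols))^2)), 0.1)
})

test_that("mixed fits recover the planted variance components", {
  cfg <- tiny_config(n_subjects = 500, n_visits = 4, noise_sd = 1,
                     random_effect_sd = c(1, 0), seed = 41)
  d <- generate_cohort(cfg)$cohort
  X <- build_design(d)
  fit <- fit_mixed(X, d$value, d$subject_id, d$age, "intercept")
  expect_lt(abs(fit$random_sd[["intercept"]] - 1) / 1, 0.15)
  expect_lt(abs(fit$residual_sd - 1) / 1, 0.15)

  # true zero variance: boundary estimate near zero
  cfg0 <- tiny_config(n_subjects = 500, n_visits = 4, noise_sd = 1,
                      random_effect_sd = c(0, 0), seed = 42)
  d0 <- generate_cohort(cfg0)$cohort
  fit0 <- fit_mixed(build_design(d0), d0$value, d0$subject_id, d0$age,
                    "intercept")
  expect_lte(fit0$random_sd[["intercept"]], 0.05)
})

test_that("a single visit per subject is a documented degeneracy, not a crash", {
  cfg <- tiny_config(n_subjects = 120, n_visits = 1, noise_sd = 1,
                     random_effect_sd = c(0.5, 0), seed = 43)
  d <- generate_cohort(cfg)$cohort
  expect_warning(
    fit <- fit_mixed(build_design(d), d$value, d$subject_id, d$age,
                     "intercept"),
    "single visit")
  expect_s3_class(fit, "biomarker_fit")
})

test_that("bic selection prefers fewer parameters on ties and checks n_obs", {
  a <- random_fit(1); a$log_likelihood <- -50; a$k <- 17; a$n_obs <- 100
  a$bic <- a$k * log(a$n_obs) - 2 * a$log_likelihood
  b <- random_fit(2); b$log_likelihood <- -50; b$k <- 18; b$n_obs <- 100
  b$variant <- "mixed_intercept"
  b$bic <- b$k * log(b$n_obs) - 2 * b$log_likelihood
  sel <- select_model_bic(list(b, a))
  expect_equal(sel$variant, "fixed_robust")
  expect_true(all(sel$bic <= attr(sel, "bic_table")$bic))

  b$n_obs <- 99
  expect_error(select_model_bic(list(a, b)), "different numbers")
})

test_that("fixed-effect estimates are equivariant under standardization", {
  set.seed(17)
  n <- 300
  d <- data.frame(age = runif(n, 40, 70), ds = sample(1:4, n, TRUE),
                  sex = rbinom(n, 1, 0.5), education = sample(6:20, n, TRUE),
                  apoe4 = sample(0:2, n, TRUE))
  X <- build_design(d)
  y <- drop(X %*% rnorm(16, 0, 0.2)) + rnorm(n)
  m <- mean(y); s <- sd(y)
  fit_raw <- fit_fixed_robust(X, y)
  fit_std <- fit_fixed_robust(X, (y - m) / s)
  mapped <- fit_raw$beta / s
  mapped[["(Intercept)"]] <- (fit_raw$beta[["(Intercept)"]] - m) / s
  expect_equal(unname(fit_std$beta), unname(mapped), tolerance = 1e-4)
})

test_that("the bic-selected variant tracks the generating process", {
  pick <- function(seed, re_sd) {
    cfg <- tiny_config(n_subjects = 250, n_visits = 4, noise_sd = 1,
                       random_effect_sd = re_sd, seed = seed)
    fit_biomarker(generate_cohort(cfg)$cohort)$variant
  }
  expect_equal(pick(1, c(0, 0)), "fixed_robust")
  expect_equal(pick(2, c(1, 0)), "mixed_intercept")
  expect_equal(pick(3, c(1, 0.5)), "mixed_intercept_slope")
})
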