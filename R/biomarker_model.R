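# Per-biomarker linear modelling: each standardized biomarker observation is
# regressed on age, disease state (DS), sex, education and apoe4 allele count
# plus all ten pairwise interactions (16 coefficients), under three variants:
#   fixed_robust          purely fixed effects, bisquare M-estimation;
#   mixed_intercept       + subject random intercept (ML);
#   mixed_intercept_slope + subject random intercept and age slope (ML).
# The variant with the smallest BIC is retained.

#' Standardize biomarkers to zero mean and unit sd
#'
#' Each biomarker is centred and scaled to sample mean 0 and sample sd 1
#' (denominator n - 1) across all retained subject-visits, so that downstream
#' abnormality values of different biomarkers are comparable. Constant
#' biomarkers (sd = 0) are excluded with a warning.
#'
#' @param cohort a cohort data.frame.
#' @return list with the standardized `cohort` and `scaling`, a data.frame
#'   (biomarker_id, mean, sd) usable for inverse mapping.
#' @export
standardize_biomarkers <- function(cohort) {
  mu <- tapply(cohort$value, cohort$biomarker_id, mean)
  sdev <- tapply(cohort$value, cohort$biomarker_id, stats::sd)
  constant <- names(sdev)[is.na(sdev) | sdev == 0]
  if (length(constant)) {
    warning("excluding constant biomarker(s): ",
            paste(constant, collapse = ", "))
    cohort <- cohort[!(cohort$biomarker_id %in% constant), , drop = FALSE]
  }
  idx <- cohort$biomarker_id
  cohort$value <- as.numeric((cohort$value - mu[idx]) / sdev[idx])
  scaling <- data.frame(biomarker_id = names(mu),
                        mean = as.numeric(mu), sd = as.numeric(sdev),
                        stringsAsFactors = FALSE)
  scaling <- scaling[!(scaling$biomarker_id %in% constant), , drop = FALSE]
  list(cohort = cohort, scaling = scaling)
}

#' Build the 16-column fixed-effects design matrix
#'
#' Columns are, in fixed order: intercept; the five main risk factors age, ds,
#' sex, education, apoe4; and their ten unordered pairwise products.
#'
#' @param data a data.frame containing the five risk factor columns.
#' @return numeric matrix with 16 named columns, one row per input row.
#' @export
build_design <- function(data) {
  missing_cov <- setdiff(MAIN_EFFECTS, names(data))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
  n <- nrow(data)
  cols <- design_colnames()
  X <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  X[, "(Intercept)"] <- 1
  for (v in MAIN_EFFECTS) X[, v] <- as.numeric(data[[v]])
  pairs <- utils::combn(MAIN_EFFECTS, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    X[, paste(a, b, sep = ":")] <- X[, a] * X[, b]
  }
  X
}

new_biomarker_fit <- function(biomarker_id, variant, beta, random_sd,
                              residual_sd, log_likelihood, k, n_obs,
                              messages = character(0)) {
  structure(list(biomarker_id = biomarker_id,
                 variant = variant,
                 beta = beta,
                 random_sd = random_sd,
                 residual_sd = residual_sd,
                 log_likelihood = log_likelihood,
                 k = k,
                 n_obs = n_obs,
                 bic = k * log(n_obs) - 2 * log_likelihood,
                 messages = messages),
            class = "biomarker_fit")
}

#' @export
print.biomarker_fit <- function(x, ...) {
  cat("<biomarker_fit>", x$biomarker_id, "variant:", x$variant,
      sprintf("BIC %.2f (n=%d, k=%d)\n", x$bic, x$n_obs, x$k))
  invisible(x)
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[seq(q$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Robust fixed-effects fit (variant one)
#'
#' Iteratively reweighted M-estimation with Tukey bisquare weights
#' (via [MASS::rlm()]; convergence when the relative coefficient change drops
#' below `acc`, at most `maxit` iterations). The log-likelihood used for BIC
#' is the Gaussian working likelihood evaluated at the final robust
#' coefficients (unweighted residual variance), an approximation that makes
#' the robust variant comparable with the ML mixed fits.
#'
#' @param X 16-column design matrix from [build_design()].
#' @param y numeric response (standardized biomarker values).
#' @param biomarker_id identifier stored in the result.
#' @param acc convergence tolerance on the relative coefficient change.
#' @param maxit maximum IRLS iterations.
#' @return a `biomarker_fit` (variant `"fixed_robust"`).
#' @export
fit_fixed_robust <- function(X, y, biomarker_id = "", acc = 1e-8, maxit = 50) {
  if (nrow(X) <= ncol(X))
    stop("need more observations (", nrow(X), ") than coefficients (",
         ncol(X), ")")
  check_full_rank(X)
  n <- length(y)
  ols <- stats::lm.fit(X, y)
  res_sd <- sqrt(sum(ols$residuals^2) / n)
  if (res_sd < 1e-10 * max(1, stats::sd(y))) {
    # Exact linear data: the M-estimate coincides with OLS; avoid the
    # zero-scale degenerate path of the IRLS loop.
    beta <- stats::setNames(ols$coefficients, colnames(X))
    ll <- -n / 2 * (log(2 * pi * max(res_sd^2, 1e-300)) + 1)
    return(new_biomarker_fit(biomarker_id, "fixed_robust", beta,
                             c(intercept = 0, age_slope = 0), res_sd,
                             ll, k = ncol(X) + 1L, n_obs = n))
  }
  fit <- suppressWarnings(
    MASS::rlm(X, y, psi = MASS::psi.bisquare, method = "M",
              maxit = maxit, acc = acc))
  r <- fit$residuals
  # Gaussian working likelihood at the robust coefficient estimates: the
  # residual variance is the unweighted mean square, so BIC values are
  # comparable with the ML mixed fits rather than deflated by downweighting.
  sigma2 <- mean(r^2)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  new_biomarker_fit(biomarker_id, "fixed_robust",
                    stats::setNames(coef(fit), colnames(X)),
                    c(intercept = 0, age_slope = 0),
                    sqrt(sigma2), ll, k = ncol(X) + 1L, n_obs = n)
}

#' Mixed-effects fit (variants two and three)
#'
#' Maximum-likelihood linear mixed model (via [lme4::lmer()], `REML = FALSE`)
#' with a subject random intercept, optionally plus a subject random age
#' slope (correlated). ML rather than REML is used so BIC values are
#' comparable across variants. For numerical conditioning the random age
#' slope is fitted on centred/scaled age and the variance components are
#' mapped back to the raw-age scale. Boundary (zero) variance estimates are
#' allowed and reported.
#'
#' @inheritParams fit_fixed_robust
#' @param subject subject identifier vector (grouping factor).
#' @param age raw age vector (years), used for the random slope.
#' @param random `"intercept"` or `"intercept_slope"`.
#' @return a `biomarker_fit` (variant `"mixed_intercept"` or
#'   `"mixed_intercept_slope"`); fitting messages (convergence, singular fit,
#'   identifiability warnings) are kept in `$messages`.
#' @export
fit_mixed <- function(X, y, subject, age,
                      random = c("intercept", "intercept_slope"),
                      biomarker_id = "") {
  random <- match.arg(random)
  if (nrow(X) <= ncol(X))
    stop("need more observations (", nrow(X), ") than coefficients (",
         ncol(X), ")")
  check_full_rank(X)
  subject <- factor(subject)
  msgs <- character(0)
  if (max(table(subject)) < 2) {
    msgs <- c(msgs, paste("every subject has a single visit: the random",
                          "intercept variance is not identifiable",
                          "separately from the residual variance"))
    warning(msgs[length(msgs)])
  }
  m <- mean(age); s <- stats::sd(age); if (!is.finite(s) || s == 0) s <- 1
  df <- data.frame(y = y, subject = subject, age_c = (age - m) / s)
  df$X <- X
  form <- if (random == "intercept") y ~ 0 + X + (1 | subject)
          else y ~ 0 + X + (1 + age_c | subject)
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = df, REML = FALSE, control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m2) {
      msgs <<- c(msgs, conditionMessage(m2))
      invokeRestart("muffleMessage")
    })
  beta <- lme4::fixef(fit)
  names(beta) <- sub("^X", "", names(beta))
  vc <- lme4::VarCorr(fit)$subject
  if (random == "intercept") {
    random_sd <- c(intercept = sqrt(vc[1, 1]), age_slope = 0)
    variant <- "mixed_intercept"
  } else {
    v00 <- vc[1, 1]; v11 <- vc[2, 2]; v01 <- vc[1, 2]
    # back-transform from the centred-age parameterization:
    # b0_raw = b0_c - (m/s) b1_c ; b1_raw = b1_c / s
    var_int <- v00 + (m / s)^2 * v11 - 2 * (m / s) * v01
    random_sd <- c(intercept = sqrt(max(var_int, 0)),
                   age_slope = sqrt(v11) / s)
    variant <- "mixed_intercept_slope"
  }
  ll <- logLik(fit)
  new_biomarker_fit(biomarker_id, variant,
                    beta[design_colnames()],
                    random_sd,
                    stats::sigma(fit),
                    as.numeric(ll), k = attr(ll, "df"), n_obs = length(y),
                    messages = msgs)
}

#' Select the best model variant by BIC
#'
#' Returns the candidate minimizing `BIC = k log(n) - 2 logLik`, where `k`
#' counts the 16 fixed coefficients plus variance components and the residual
#' variance. Ties go to the candidate with fewest parameters.
#'
#' @param candidates list of `biomarker_fit` objects fitted on identical data.
#' @return the selected `biomarker_fit`, with a `bic_table` attribute listing
#'   every candidate's variant, k and BIC.
#' @export
select_model_bic <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  n_obs <- vapply(candidates, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1)
    stop("candidates were fitted on different numbers of observations: ",
         paste(n_obs, collapse = ", "))
  bics <- vapply(candidates, function(f) f$bic, numeric(1))
  ks <- vapply(candidates, function(f) f$k, numeric(1))
  best <- order(bics, ks)[1]
  out <- candidates[[best]]
  attr(out, "bic_table") <- data.frame(
    variant = vapply(candidates, function(f) f$variant, character(1)),
    k = ks, bic = bics, stringsAsFactors = FALSE)
  out
}

#' Fit one biomarker under the requested variants and select by BIC
#'
#' @param data long-format rows for a single biomarker: risk factor columns
#'   plus `subject_id` and `value`.
#' @param variants subset of `c("fixed_robust", "mixed_intercept",
#'   "mixed_intercept_slope")`.
#' @param biomarker_id identifier stored in the result.
#' @return the BIC-selected `biomarker_fit`.
#' @export
fit_biomarker <- function(data,
                          variants = c("fixed_robust", "mixed_intercept",
                                       "mixed_intercept_slope"),
                          biomarker_id = data$biomarker_id[1]) {
  variants <- match.arg(variants, several.ok = TRUE)
  X <- build_design(data)
  y <- data$value
  fits <- lapply(variants, function(v) {
    switch(v,
           fixed_robust = fit_fixed_robust(X, y, biomarker_id),
           mixed_intercept = fit_mixed(X, y, data$subject_id, data$age,
                                       "intercept", biomarker_id),
           mixed_intercept_slope = fit_mixed(X, y, data$subject_id, data$age,
                                             "intercept_slope", biomarker_id))
  })
  select_model_bic(fits)
}

#' Fit every biomarker in a cohort
#'
#' @param cohort a standardized cohort data.frame.
#' @inheritParams fit_biomarker
#' @return named list of `biomarker_fit` objects (class `biomarker_fits`).
#' @export
fit_all_biomarkers <- function(cohort,
                               variants = c("fixed_robust", "mixed_intercept",
                                            "mixed_intercept_slope")) {
  parts <- split(cohort, cohort$biomarker_id)
  fits <- lapply(parts, fit_biomarker, variants = variants)
  structure(fits, class = "biomarker_fits")
}

#' Summarize a set of biomarker fits as a table
#'
#' @param fits a `biomarker_fits` list from [fit_all_biomarkers()].
#' @return data.frame with one row per biomarker: variant, the 16
#'   coefficients, random-effect sds, residual sd, log-likelihood and BIC.
#' @export
fits_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    co <- as.list(f$beta)
    names(co) <- gsub("[():]", "_", names(co))
    cbind(data.frame(biomarker_id = f$biomarker_id, variant = f$variant,
                     stringsAsFactors = FALSE),
          as.data.frame(co, optional = TRUE),
          data.frame(sd_intercept = f$random_sd[["intercept"]],
                     sd_age_slope = f$random_sd[["age_slope"]],
                     residual_sd = f$residual_sd,
                     log_likelihood = f$log_likelihood,
                     k = f$k, n_obs = f$n_obs, bic = f$bic))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
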