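# Characteristic trajectories: the fitted fixed-effects predictor is averaged
# (marginalized) over the nuisance covariates sex, education and apoe4,
# leaving a function of age and disease state only, which is then evaluated
# along clinical transitions on a weekly age grid spanning 30 years.

#' Weekly age grid over the progression interval
#'
#' @param n_points number of grid points; the default 1560 is one point per
#'   week over 30 years.
#' @param range age range in years, endpoints inclusive.
#' @return strictly increasing numeric vector of ages.
#' @export
age_grid <- function(n_points = 1560, range = c(40, 70)) {
  seq(range[1], range[2], length.out = n_points)
}

#' Covariate domains of a cohort
#'
#' Extracts, at the subject level, the observed categories of sex and apoe4,
#' the observed education range, and the joint empirical covariate table used
#' by empirical-frequency marginalization.
#'
#' @param cohort a cohort data.frame.
#' @return list with `sex`, `apoe4` (observed categories), `education`
#'   (min, max) and `subject_covariates` (one row per subject).
#' @export
covariate_domains <- function(cohort) {
  sub <- unique(cohort[, c("subject_id", "sex", "education", "apoe4")])
  list(sex = sort(unique(sub$sex)),
       apoe4 = sort(unique(sub$apoe4)),
       education = range(sub$education),
       subject_covariates = sub)
}

#' Marginalize a fitted biomarker model over nuisance covariates
#'
#' Averages the fixed-effects predictor over sex, education and apoe4,
#' yielding a predictor `g(age, ds)` of age and disease state only; random
#' effects are set to their zero population mean. With `weighting =
#' "uniform"` (the default) sex and apoe4 are averaged uniformly over their
#' observed categories and education uniformly over its observed min-max
#' range (the predictor is linear in education, so this equals evaluating at
#' the range midpoint). With `weighting = "empirical"` the joint empirical
#' distribution of subject covariates is used.
#'
#' Because the model is linear with pairwise interactions, the marginal
#' predictor is exactly `g(age, ds) = a + b age + c ds + d age ds` with
#' covariate-averaged coefficients.
#'
#' @param model a `biomarker_fit`.
#' @param domains covariate domains from [covariate_domains()].
#' @param weighting `"uniform"` or `"empirical"`.
#' @return an object of class `marginal_predictor` with the four coefficients
#'   and a provenance record; evaluate it with [predict()].
#' @export
marginalize <- function(model, domains, weighting = c("uniform", "empirical")) {
  weighting <- match.arg(weighting)
  b <- model$beta
  if (length(b) != 16 || anyNA(b))
    stop("model must carry all 16 fixed-effect coefficients")
  if (weighting == "uniform") {
    if (!length(domains$sex) || !length(domains$apoe4) ||
        !length(domains$education))
      stop("empty covariate domain")
    grid <- expand.grid(sex = domains$sex, apoe4 = domains$apoe4)
    grid$education <- mean(domains$education)
    w <- rep(1 / nrow(grid), nrow(grid))
  } else {
    grid <- domains$subject_covariates
    if (!nrow(grid)) stop("empty covariate domain")
    w <- rep(1 / nrow(grid), nrow(grid))
  }
  sx <- grid$sex; ed <- grid$education; ap <- grid$apoe4
  a <- b[["(Intercept)"]] + b[["sex"]] * sx + b[["education"]] * ed +
    b[["apoe4"]] * ap + b[["sex:education"]] * sx * ed +
    b[["sex:apoe4"]] * sx * ap + b[["education:apoe4"]] * ed * ap
  b_age <- b[["age"]] + b[["age:sex"]] * sx + b[["age:education"]] * ed +
    b[["age:apoe4"]] * ap
  c_ds <- b[["ds"]] + b[["ds:sex"]] * sx + b[["ds:education"]] * ed +
    b[["ds:apoe4"]] * ap
  structure(list(biomarker_id = model$biomarker_id,
                 coef = c(intercept = sum(w * a),
                          age = sum(w * b_age),
                          ds = sum(w * c_ds),
                          `age:ds` = b[["age:ds"]]),
                 weighting = weighting,
                 domains = domains[c("sex", "education", "apoe4")]),
            class = "marginal_predictor")
}

#' @export
predict.marginal_predictor <- function(object, age, ds, ...) {
  co <- object$coef
  co[["intercept"]] + co[["age"]] * age + co[["ds"]] * ds +
    co[["age:ds"]] * age * ds
}

#' Disease-state path along a clinical transition
#'
#' Returns DS(t) on the age grid: constant 1 for the healthy transition;
#' otherwise a ramp from DS = 1 at the first grid age to the transition's
#' terminal state at the last. The linear shape interpolates linearly; the
#' sigmoid shape follows a logistic ramp (midpoint and 5-to-95-percent rise
#' width in years set by `sigmoid_params`), affinely normalized so the grid
#' endpoints attain the terminal values exactly.
#'
#' @param transition one of `"HC-HC"`, `"HC-EMCI"`, `"HC-LMCI"`, `"HC-LOAD"`.
#' @param shape `"linear"` or `"sigmoid"`.
#' @param grid age grid from [age_grid()].
#' @param sigmoid_params list(midpoint, width) in years.
#' @return numeric vector of DS values on the grid.
#' @export
ds_path <- function(transition, shape = c("linear", "sigmoid"),
                    grid = age_grid(),
                    sigmoid_params = list(midpoint = 55, width = 20)) {
  shape <- match.arg(shape)
  terminal <- terminal_ds(transition)
  if (terminal == 1) return(rep(1, length(grid)))
  a0 <- grid[1]; a1 <- grid[length(grid)]
  if (shape == "linear") {
    1 + (terminal - 1) * (grid - a0) / (a1 - a0)
  } else {
    if (is.null(sigmoid_params$midpoint) || is.null(sigmoid_params$width))
      stop("sigmoid_params must provide midpoint and width")
    k <- 2 * log(19) / sigmoid_params$width
    sg <- function(t) 1 / (1 + exp(-k * (t - sigmoid_params$midpoint)))
    s <- (sg(grid) - sg(a0)) / (sg(a1) - sg(a0))
    1 + (terminal - 1) * s
  }
}

#' Generate a characteristic trajectory for one clinical transition
#'
#' Evaluates a marginal predictor along the DS path of a transition on the
#' weekly age grid.
#'
#' @param predictor a `marginal_predictor` from [marginalize()].
#' @inheritParams ds_path
#' @return data.frame (biomarker_id, transition, age, ds, value), one row per
#'   grid point.
#' @export
generate_trajectory <- function(predictor, transition,
                                shape = c("linear", "sigmoid"),
                                grid = age_grid(),
                                sigmoid_params = list(midpoint = 55,
                                                      width = 20)) {
  shape <- match.arg(shape)
  ds <- ds_path(transition, shape, grid, sigmoid_params)
  data.frame(biomarker_id = predictor$biomarker_id,
             transition = transition,
             age = grid,
             ds = ds,
             value = predict(predictor, grid, ds),
             stringsAsFactors = FALSE)
}

#' Trajectories of many biomarkers over all clinical transitions
#'
#' @param predictors list of `marginal_predictor` objects.
#' @param transitions clinical transitions to cover.
#' @inheritParams generate_trajectory
#' @return long data.frame of stacked trajectories.
#' @export
trajectory_set <- function(predictors, transitions = TRANSITIONS,
                           shape = c("linear", "sigmoid"),
                           grid = age_grid(),
                           sigmoid_params = list(midpoint = 55, width = 20)) {
  shape <- match.arg(shape)
  out <- lapply(predictors, function(p) {
    do.call(rbind, lapply(transitions, function(tr)
      generate_trajectory(p, tr, shape, grid, sigmoid_params)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
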