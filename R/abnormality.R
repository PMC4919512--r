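# Abnormality metrics: each biomarker's diseased-transition trajectory is
# compared pointwise with its healthy-aging (HC-HC) trajectory; the absolute
# difference curve is integrated over the 30-year span and normalized so the
# most abnormal biomarker of the comparison set scores 1.

#' Abnormality curve of a diseased transition
#'
#' Pointwise absolute difference between a diseased trajectory and the
#' healthy-aging trajectory of the same biomarker on the same age grid. As
#' biomarkers are standardized beforehand, curves of different biomarkers are
#' directly comparable.
#'
#' @param disease trajectory data.frame for a diseased transition.
#' @param healthy trajectory data.frame for the HC-HC transition.
#' @return data.frame (biomarker_id, transition, age, value) with
#'   non-negative values.
#' @export
abnormality_curve <- function(disease, healthy) {
  if (!identical(unique(disease$biomarker_id), unique(healthy$biomarker_id)))
    stop("disease and healthy trajectories are for different biomarkers")
  if (nrow(disease) != nrow(healthy) ||
      max(abs(disease$age - healthy$age)) > 1e-9)
    stop("disease and healthy trajectories are on different age grids")
  data.frame(biomarker_id = disease$biomarker_id,
             transition = disease$transition,
             age = disease$age,
             value = abs(disease$value - healthy$value),
             stringsAsFactors = FALSE)
}

#' Abnormality curves for every biomarker and diseased transition
#'
#' @param trajectories long trajectory data.frame containing, per biomarker,
#'   the HC-HC transition plus at least one diseased transition.
#' @return long data.frame of abnormality curves.
#' @export
abnormality_curves <- function(trajectories) {
  out <- lapply(split(trajectories, trajectories$biomarker_id), function(d) {
    healthy <- d[d$transition == "HC-HC", , drop = FALSE]
    if (!nrow(healthy))
      stop("biomarker ", d$biomarker_id[1], " lacks an HC-HC trajectory")
    diseased <- d[d$transition != "HC-HC", , drop = FALSE]
    do.call(rbind, lapply(split(diseased, diseased$transition),
                          abnormality_curve, healthy = healthy))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Total abnormality indices over a set of curves
#'
#' The raw abnormality of each curve is its trapezoidal integral over the age
#' grid; dividing by the shared normalization constant `K` (the maximum raw
#' area in the set) guarantees a maximum total abnormality index of 1 across
#' the considered biomarkers.
#'
#' @param curves long abnormality-curve data.frame (one transition).
#' @return data.frame (biomarker_id, raw_area, total_index) with attribute
#'   `K`; if every curve is identically zero, indices are reported as 0 with
#'   a warning.
#' @export
total_abnormality_index <- function(curves) {
  if (!nrow(curves)) stop("empty curve set")
  parts <- split(curves, curves$biomarker_id)
  raw <- vapply(parts, function(d) trapz(d$age, d$value), numeric(1))
  K <- max(raw)
  if (K <= 0) {
    warning("all abnormality curves are zero; indices reported as 0")
    idx <- rep(0, length(raw))
  } else idx <- raw / K
  out <- data.frame(biomarker_id = names(raw),
                    raw_area = unname(raw),
                    total_index = unname(idx),
                    stringsAsFactors = FALSE)
  attr(out, "K") <- K
  out
}

#' Stage ages on a transition's disease-state path
#'
#' The EMCI and LMCI time points are the first grid ages at which the DS path
#' of the HC-LOAD transition reaches 2 and 3; under the linear ramp these are
#' ages 50 and 60.
#'
#' @inheritParams ds_path
#' @return named numeric vector c(emci, lmci).
#' @export
stage_ages_from_path <- function(shape = c("linear", "sigmoid"),
                                 grid = age_grid(),
                                 sigmoid_params = list(midpoint = 55,
                                                       width = 20)) {
  shape <- match.arg(shape)
  if (shape == "linear") {
    a0 <- grid[1]; a1 <- grid[length(grid)]
    return(c(emci = a0 + (a1 - a0) / 3, lmci = a0 + 2 * (a1 - a0) / 3))
  }
  ds <- ds_path("HC-LOAD", shape, grid, sigmoid_params)
  c(emci = grid[which(ds >= 2)[1]], lmci = grid[which(ds >= 3)[1]])
}

#' Intermediate abnormality indices of one curve
#'
#' Evaluates the abnormality integral only up to the EMCI and LMCI time
#' points, divided by the same normalization constant `K` as the total index.
#' These partial indices avoid biasing against biomarkers that are abnormal
#' early but renormalize later in the progression.
#'
#' @param curve abnormality-curve data.frame of a single biomarker.
#' @param stage_ages named vector c(emci, lmci) inside the grid.
#' @param K shared normalization constant from [total_abnormality_index()].
#' @return named numeric vector c(emci, lmci).
#' @export
intermediate_indices <- function(curve, stage_ages = c(emci = 50, lmci = 60),
                                 K) {
  if (K <= 0) return(c(emci = 0, lmci = 0))
  c(emci = trapz_to(curve$age, curve$value, stage_ages[["emci"]]) / K,
    lmci = trapz_to(curve$age, curve$value, stage_ages[["lmci"]]) / K)
}

#' Total and intermediate abnormality indices for a curve set
#'
#' Combines [total_abnormality_index()] and [intermediate_indices()] under a
#' shared normalization constant. With `k_scope = "all"` (default) one `K` is
#' shared across every biomarker in the set; with `k_scope = "group"` a
#' separate `K` is computed within each group given by `groups` (e.g. CSF vs
#' plasma panels).
#'
#' @inheritParams total_abnormality_index
#' @inheritParams intermediate_indices
#' @param k_scope `"all"` or `"group"`.
#' @param groups named character vector mapping biomarker_id to group, needed
#'   for `k_scope = "group"`.
#' @return data.frame (biomarker_id, raw_area, total_index, emci_index,
#'   lmci_index, K).
#' @export
abnormality_index_table <- function(curves,
                                    stage_ages = c(emci = 50, lmci = 60),
                                    k_scope = c("all", "group"),
                                    groups = NULL) {
  k_scope <- match.arg(k_scope)
  if (k_scope == "group") {
    if (is.null(groups)) stop("k_scope = 'group' requires a groups mapping")
    parts <- split(curves, groups[curves$biomarker_id])
    out <- do.call(rbind, lapply(parts, abnormality_index_table,
                                 stage_ages = stage_ages, k_scope = "all"))
    rownames(out) <- NULL
    return(out)
  }
  totals <- total_abnormality_index(curves)
  K <- attr(totals, "K")
  inter <- t(vapply(split(curves, curves$biomarker_id),
                    intermediate_indices, numeric(2),
                    stage_ages = stage_ages, K = K))
  out <- cbind(totals,
               data.frame(emci_index = inter[totals$biomarker_id, "emci"],
                          lmci_index = inter[totals$biomarker_id, "lmci"],
                          K = K))
  rownames(out) <- NULL
  out
}
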