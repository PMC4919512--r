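# Multifactorial ordering: pairwise dominance of factors across regions and
# time points, regional vulnerability weights, and vulnerability-weighted
# normalized factor curves from which a temporal ordering is read off.

#' Pairwise hierarchical dominance matrix of imaging factors
#'
#' For each pair of factors, each brain region and each time point of the
#' HC-LOAD abnormality curves, the factor with the strictly higher
#' abnormality scores 1 (ties score 0.5 each). Entry `H[i, j]` is the
#' percentage of region-time points at which factor `j` exceeded factor `i`;
#' rows and columns are reordered so the predominating factors come first.
#'
#' @param curves long abnormality-curve data.frame for the imaging biomarkers
#'   (HC-LOAD transition), with ids of the form `<factor>.<region>`.
#' @param factor_names the imaging factor names.
#' @return object of class `hierarchical_matrix`: list with `H` (reordered
#'   percentage matrix, `H[i,j] + H[j,i] = 100` off-diagonal, zero diagonal),
#'   `ordering` (factors by decreasing dominance), `n_regions`,
#'   `n_timepoints`.
#' @export
hierarchical_matrix <- function(curves,
                                factor_names = c("vascular", "amyloid",
                                                 "metabolic", "functional",
                                                 "structural")) {
  meta <- parse_biomarker_ids(unique(curves$biomarker_id), factor_names)
  meta <- meta[meta$imaging, , drop = FALSE]
  curves <- curves[curves$biomarker_id %in% meta$biomarker_id, , drop = FALSE]
  if (!nrow(curves)) stop("no imaging biomarker curves found")
  regions <- sort(unique(meta$region))
  ages <- sort(unique(curves$age))
  arrays <- lapply(factor_names, function(f) {
    ids <- meta$biomarker_id[meta$factor == f]
    if (!setequal(meta$region[meta$factor == f], regions))
      stop("factor ", f, " does not cover the common region set")
    d <- curves[curves$biomarker_id %in% ids, , drop = FALSE]
    if (nrow(d) != length(regions) * length(ages))
      stop("factor ", f, " is not on the common region x age grid")
    m <- matrix(NA_real_, length(regions), length(ages),
                dimnames = list(regions, NULL))
    reg <- meta$region[match(d$biomarker_id, meta$biomarker_id)]
    m[cbind(match(reg, regions), match(d$age, ages))] <- d$value
    m
  })
  names(arrays) <- factor_names
  nf <- length(factor_names)
  H <- matrix(0, nf, nf, dimnames = list(factor_names, factor_names))
  for (i in seq_len(nf - 1)) {
    for (j in seq((i + 1), nf)) {
      ai <- arrays[[i]]; aj <- arrays[[j]]
      wins_j <- mean(aj > ai) + 0.5 * mean(aj == ai)
      H[i, j] <- 100 * wins_j
      H[j, i] <- 100 * (1 - wins_j)
    }
  }
  dominance <- colSums(H)
  ord <- order(-dominance, factor_names)
  structure(list(H = H[ord, ord, drop = FALSE],
                 ordering = factor_names[ord],
                 dominance = dominance[ord],
                 n_regions = length(regions),
                 n_timepoints = length(ages)),
            class = "hierarchical_matrix")
}

#' @export
print.hierarchical_matrix <- function(x, ...) {
  cat("<hierarchical_matrix>", x$n_regions, "regions x", x$n_timepoints,
      "time points\nordering:", paste(x$ordering, collapse = " > "), "\n")
  print(round(x$H, 1))
  invisible(x)
}

#' Regional vulnerability weights
#'
#' A region's vulnerability is the sum of its total abnormality indices
#' across all biological factors; weights are normalized to sum 1 and are
#' used to weight regions when averaging abnormality curves within a factor.
#'
#' @param index_table abnormality index table restricted to imaging
#'   biomarkers (ids `<factor>.<region>`), e.g. from
#'   [abnormality_index_table()].
#' @inheritParams hierarchical_matrix
#' @return data.frame (region, raw_sum, weight) with weights summing to 1.
#' @export
regional_vulnerability <- function(index_table,
                                   factor_names = c("vascular", "amyloid",
                                                    "metabolic", "functional",
                                                    "structural")) {
  meta <- parse_biomarker_ids(index_table$biomarker_id, factor_names)
  meta <- meta[meta$imaging, , drop = FALSE]
  tab <- index_table[index_table$biomarker_id %in% meta$biomarker_id, ,
                     drop = FALSE]
  reg <- meta$region[match(tab$biomarker_id, meta$biomarker_id)]
  fac <- meta$factor[match(tab$biomarker_id, meta$biomarker_id)]
  counts <- table(reg, fac)
  if (any(counts != 1))
    stop("every region needs exactly one index per factor; missing or ",
         "duplicated factor-region pairs found")
  raw <- tapply(tab$total_index, reg, sum)
  total <- sum(raw)
  w <- if (total > 0) raw / total else rep(1 / length(raw), length(raw))
  data.frame(region = names(raw), raw_sum = as.numeric(raw),
             weight = as.numeric(w), stringsAsFactors = FALSE)
}

#' Vulnerability-weighted normalized factor curves
#'
#' For each biological factor the regional abnormality curves are averaged
#' with the regional vulnerability weights (a convex combination across
#' regions); optional scalar biomarker curves (cognition, CSF/plasma
#' analytes) pass through unweighted. All curves are then divided by the
#' single global maximum across the set, so values lie in [0, 1] and at
#' least one curve attains 1.
#'
#' @inheritParams hierarchical_matrix
#' @param weights data.frame from [regional_vulnerability()].
#' @param scalar_curves optional long abnormality-curve data.frame of scalar
#'   biomarkers on the same grid.
#' @return long data.frame (curve_id, age, value) with attribute
#'   `global_max`; if every curve is zero a warning is raised and values stay
#'   zero.
#' @export
factor_average_curves <- function(curves, weights, scalar_curves = NULL,
                                  factor_names = c("vascular", "amyloid",
                                                   "metabolic", "functional",
                                                   "structural")) {
  meta <- parse_biomarker_ids(unique(curves$biomarker_id), factor_names)
  meta <- meta[meta$imaging, , drop = FALSE]
  missing_w <- setdiff(meta$region, weights$region)
  if (length(missing_w))
    stop("weights missing for region(s): ", paste(missing_w, collapse = ", "))
  wmap <- stats::setNames(weights$weight, weights$region)
  ages <- sort(unique(curves$age))
  fac_curves <- lapply(factor_names, function(f) {
    ids <- meta$biomarker_id[meta$factor == f]
    d <- curves[curves$biomarker_id %in% ids, , drop = FALSE]
    reg <- meta$region[match(d$biomarker_id, meta$biomarker_id)]
    v <- tapply(d$value * wmap[reg], match(d$age, ages), sum)
    data.frame(curve_id = f, age = ages, value = as.numeric(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fac_curves)
  if (!is.null(scalar_curves) && nrow(scalar_curves)) {
    sc <- data.frame(curve_id = scalar_curves$biomarker_id,
                     age = scalar_curves$age,
                     value = scalar_curves$value,
                     stringsAsFactors = FALSE)
    out <- rbind(out, sc)
  }
  gmax <- max(out$value)
  if (gmax > 0) out$value <- out$value / gmax
  else warning("all curves are zero; skipping normalization")
  attr(out, "global_max") <- gmax
  rownames(out) <- NULL
  out
}

#' Rank factors (and scalar biomarkers) by abnormality
#'
#' Sorts the curves of a normalized factor curve set by decreasing area under
#' the curve (default) or by their value at a fixed age. Exact ties are
#' broken alphabetically and flagged.
#'
#' @param curve_set long data.frame from [factor_average_curves()].
#' @param by `"area"` or `"at_age"`.
#' @param at_age age at which curves are compared when `by = "at_age"`.
#' @return character vector of curve ids in decreasing order, with
#'   attributes `scores` and `ties` (logical).
#' @export
rank_factors <- function(curve_set, by = c("area", "at_age"), at_age = NULL) {
  by <- match.arg(by)
  parts <- split(curve_set, curve_set$curve_id)
  score <- if (by == "area") {
    vapply(parts, function(d) trapz(d$age, d$value), numeric(1))
  } else {
    if (is.null(at_age)) stop("by = 'at_age' requires at_age")
    vapply(parts, function(d) stats::approx(d$age, d$value, at_age)$y,
           numeric(1))
  }
  ord <- order(-score, names(score))
  out <- names(score)[ord]
  attr(out, "scores") <- score[ord]
  attr(out, "ties") <- anyDuplicated(score) > 0
  out
}
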