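# Internal helpers shared across modules.

# Canonical column order of the fixed-effects design: intercept, the five main
# risk factors, then the ten unordered pairwise interactions.
MAIN_EFFECTS <- c("age", "ds", "sex", "education", "apoe4")

design_colnames <- function() {
  pairs <- utils::combn(MAIN_EFFECTS, 2)
  c("(Intercept)", MAIN_EFFECTS, paste(pairs[1, ], pairs[2, ], sep = ":"))
}

COHORT_COLUMNS <- c("subject_id", "visit", "age", "sex", "education",
                    "apoe4", "ds", "biomarker_id", "value")

DS_LEVELS <- c(HC = 1, EMCI = 2, LMCI = 3, LOAD = 4)
TRANSITIONS <- c("HC-HC", "HC-EMCI", "HC-LMCI", "HC-LOAD")

terminal_ds <- function(transition) {
  out <- c("HC-HC" = 1, "HC-EMCI" = 2, "HC-LMCI" = 3, "HC-LOAD" = 4)[transition]
  if (anyNA(out)) {
    stop("unknown transition(s): ",
         paste(setdiff(transition, names(out)), collapse = ", "),
         "; expected one of ", paste(TRANSITIONS, collapse = ", "))
  }
  unname(out)
}

# Independent named random streams derived from one root seed, so that e.g.
# planting converters does not perturb the cohort draws.
stream_seed <- function(seed, stream) {
  streams <- c(cohort = 1L, converters = 2L, outliers = 3L, bootstrap = 4L,
               qc = 5L, misc = 6L)
  idx <- streams[[stream]]
  as.integer((as.numeric(seed) + 7919 * idx) %% (2^31 - 1))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Trapezoidal integral of y over x truncated at xmax, with linear
# interpolation of y at the cut point when xmax falls between grid nodes.
trapz_to <- function(x, y, xmax) {
  if (xmax < x[1] || xmax > x[length(x)])
    stop("truncation point ", xmax, " lies outside the grid [",
         x[1], ", ", x[length(x)], "]")
  keep <- x <= xmax
  xs <- x[keep]
  ys <- y[keep]
  if (xmax > xs[length(xs)]) {
    ycut <- stats::approx(x, y, xout = xmax)$y
    xs <- c(xs, xmax)
    ys <- c(ys, ycut)
  }
  trapz(xs, ys)
}

# Ledoit-Wolf-style shrinkage of a sample covariance toward a scaled identity
# target; keeps Mahalanobis distances well defined when n is small relative
# to the feature dimension.
shrink_cov <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("need at least 2 observations to estimate a covariance")
  s <- stats::cov(x)
  mu <- mean(diag(s))
  target <- diag(mu, p)
  xc <- sweep(x, 2, colMeans(x))
  # Ledoit-Wolf (2004) optimal intensity for the scaled-identity target.
  d2 <- sum((s - target)^2)
  b2 <- 0
  for (i in seq_len(n)) {
    b2 <- b2 + sum((tcrossprod(xc[i, ]) - s)^2)
  }
  b2 <- b2 / n^2
  lambda <- if (d2 > 0) min(1, max(0, b2 / d2)) else 1
  list(sigma = (1 - lambda) * s + lambda * target, lambda = lambda)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Imaging biomarker ids are "<factor>.<region>"; anything else is a scalar
# biomarker. Returns a data.frame(biomarker_id, factor, region, imaging).
parse_biomarker_ids <- function(ids, factor_names) {
  ids <- as.character(unique(ids))
  m <- regmatches(ids, regexec("^([^.]+)\\.(.+)$", ids))
  fac <- vapply(m, function(g) if (length(g) == 3L) g[2] else NA_character_, "")
  reg <- vapply(m, function(g) if (length(g) == 3L) g[3] else NA_character_, "")
  imaging <- !is.na(fac) & fac %in% factor_names
  data.frame(biomarker_id = ids,
             factor = ifelse(imaging, fac, NA_character_),
             region = ifelse(imaging, reg, NA_character_),
             imaging = imaging,
             stringsAsFactors = FALSE)
}

region_labels <- function(n_regions) sprintf("r%02d", seq_len(n_regions))

imaging_biomarker_ids <- function(factor_names, n_regions) {
  as.vector(t(outer(factor_names, region_labels(n_regions), paste, sep = ".")))
}
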