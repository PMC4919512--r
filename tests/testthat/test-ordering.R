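regional_curves <- function(value_fun, factors = c("f1", "f2"),
                            regions = c("r1", "r2"), grid = age_grid(30)) {
  do.call(rbind, lapply(factors, function(f)
    do.call(rbind, lapply(regions, function(r)
      data.frame(biomarker_id = paste(f, r, sep = "."),
                 transition = "HC-LOAD", age = grid,
                 value = value_fun(f, r, grid),
                 stringsAsFactors = FALSE)))))
}

test_that("the hierarchical matrix counts strict wins and splits ties", {
  # f1 strictly above f2 everywhere
  cur <- regional_curves(function(f, r, g) if (f == "f1") g else g - 5)
  hm <- hierarchical_matrix(cur, factor_names = c("f1", "f2"))
  expect_equal(hm$H["f2", "f1"], 100)
  expect_equal(hm$H["f1", "f2"], 0)
  expect_equal(hm$ordering, c("f1", "f2"))
  expect_equal(diag(hm$H), c(f1 = 0, f2 = 0))

  tied <- regional_curves(function(f, r, g) g)
  hm2 <- hierarchical_matrix(tied, factor_names = c("f1", "f2"))
  expect_equal(hm2$H["f1", "f2"], 50)
  expect_equal(hm2$H["f2", "f1"], 50)
})

test_that("matrix complementarity holds on random inputs", {
  set.seed(55)
  for (rep in 1:5) {
    cur <- regional_curves(function(f, r, g) rnorm(length(g)),
                           factors = paste0("f", 1:4),
                           regions = paste0("r", 1:3))
    hm <- hierarchical_matrix(cur, factor_names = paste0("f", 1:4))
    off <- hm$H + t(hm$H)
    expect_equal(unname(off[upper.tri(off)]), rep(100, 6))
    expect_equal(unname(diag(hm$H)), rep(0, 4))
  }
})

test_that("separable inputs order factors by their mean level", {
  levels <- c(f1 = 4, f2 = 3, f3 = 2, f4 = 1.5, f5 = 1)
  cur <- regional_curves(function(f, r, g) rep(levels[[f]], length(g)),
                         factors = names(levels), regions = paste0("r", 1:3))
  hm <- hierarchical_matrix(cur, factor_names = names(levels))
  expect_equal(dim(hm$H), c(5, 5))
  expect_equal(hm$ordering, names(sort(levels, decreasing = TRUE)))
})

test_that("regional vulnerability normalizes summed indices", {
  idx <- data.frame(biomarker_id = c("f1.rA", "f2.rA", "f1.rB", "f2.rB"),
                    total_index = c(1, 2, 0.5, 0.5),
                    stringsAsFactors = FALSE)
  w <- regional_vulnerability(idx, factor_names = c("f1", "f2"))
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_equal(w$weight[w$region == "rA"], 0.75)
  expect_equal(w$weight[w$region == "rB"], 0.25)

  zero <- data.frame(biomarker_id = c("f1.rA", "f1.rB"),
                     total_index = c(0, 1), stringsAsFactors = FALSE)
  wz <- regional_vulnerability(zero, factor_names = "f1")
  expect_equal(wz$weight[wz$region == "rA"], 0)

  uni <- data.frame(biomarker_id = c("f1.rA", "f1.rB"),
                    total_index = c(0.4, 0.4), stringsAsFactors = FALSE)
  wu <- regional_vulnerability(uni, factor_names = "f1")
  expect_equal(wu$weight, c(0.5, 0.5))

  expect_error(regional_vulnerability(idx[-1, ], c("f1", "f2")), "region")
})

test_that("factor curves are weighted convex combinations, globally normalized", {
  g <- age_grid(30)
  cur <- regional_curves(function(f, r, g) if (r == "rA") rep(4, length(g))
                         else rep(0, length(g)),
                         factors = "f1", regions = c("rA", "rB"), grid = g)
  w <- data.frame(region = c("rA", "rB"), weight = c(0.75, 0.25))
  fc <- factor_average_curves(cur, w, factor_names = "f1")
  # weighted value 3 before normalization; global max then rescales to 1
  expect_equal(attr(fc, "global_max"), 3)
  expect_equal(unique(fc$value), 1)

  # convexity: weighted curve between regional min and max at every age
  set.seed(9)
  cur2 <- regional_curves(function(f, r, g) abs(rnorm(length(g))),
                          factors = "f1", regions = paste0("r", 1:4),
                          grid = g)
  w2 <- data.frame(region = paste0("r", 1:4), weight = rep(0.25, 4))
  fc2 <- factor_average_curves(cur2, w2, factor_names = "f1")
  gm <- attr(fc2, "global_max")
  rng <- tapply(cur2$value, cur2$age, range)
  for (i in seq_along(g)) {
    r <- rng[[as.character(g[i])]]
    v <- fc2$value[fc2$age == g[i]] * gm
    expect_gte(v, r[1] - 1e-12)
    expect_lte(v, r[2] + 1e-12)
  }

  expect_warning(factor_average_curves(
    regional_curves(function(f, r, g) rep(0, length(g)), factors = "f1",
                    regions = c("rA", "rB"), grid = g),
    w, factor_names = "f1"), "zero")
})

test_that("scalar biomarker curves pass through unweighted", {
  g <- age_grid(30)
  cur <- regional_curves(function(f, r, g) rep(2, length(g)),
                         factors = "f1", regions = c("rA", "rB"), grid = g)
  w <- data.frame(region = c("rA", "rB"), weight = c(0.5, 0.5))
  scal <- data.frame(biomarker_id = "mmse", transition = "HC-LOAD", age = g,
                     value = rep(4, length(g)), stringsAsFactors = FALSE)
  fc <- factor_average_curves(cur, w, scalar_curves = scal,
                              factor_names = "f1")
  expect_equal(unique(fc$value[fc$curve_id == "mmse"]), 1)
  expect_equal(unique(fc$value[fc$curve_id == "f1"]), 0.5)
})

test_that("factors rank by area with flagged alphabetical tie-breaks", {
  g <- age_grid(30)
  cs <- do.call(rbind, lapply(list(c("a", 5), c("b", 3), c("c", 1)),
                              function(x)
                                data.frame(curve_id = x[1], age = g,
                                           value = as.numeric(x[2]),
                                           stringsAsFactors = FALSE)))
  r <- rank_factors(cs)
  expect_equal(as.character(r), c("a", "b", "c"))
  expect_false(attr(r, "ties"))

  tie <- rbind(cs, data.frame(curve_id = "d", age = g, value = 5,
                              stringsAsFactors = FALSE))
  rt <- rank_factors(tie)
  expect_equal(as.character(rt)[1:2], c("a", "d"))
  expect_true(attr(rt, "ties"))

  at <- rank_factors(cs, by = "at_age", at_age = 50)
  expect_equal(as.character(at), c("a", "b", "c"))
})

test_that("the end-to-end pipeline recovers a planted factor ordering", {
  cfg <- synthetic_config(n_subjects = 300, n_visits = 4, n_regions = 4,
                          scalar_biomarker_names = character(0),
                          ds_effects = c(vascular = 1.25, amyloid = 1,
                                         metabolic = 0.75, functional = 0.5,
                                         structural = 0.25),
                          noise_sd = 1, random_effect_sd = c(0.5, 0.02),
                          seed = 77)
  sim <- generate_cohort(cfg)
  qc <- run_qc(sim$cohort)
  std <- standardize_biomarkers(qc$cohort)
  res <- progression_analysis(std$cohort, variants = "fixed_robust")
  expect_equal(res$factor_ranking, sim$truth$planted_factor_order)
  expect_equal(res$hierarchy$ordering, sim$truth$planted_factor_order)
})
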