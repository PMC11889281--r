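test_that("correlation test matches the closed-form t transform", {
  # fixture of 10 printed pairs, checked against the textbook formulas
  x <- c(1.2, 2.3, 0.7, 3.1, 2.8, 1.9, 0.4, 2.2, 3.6, 1.1)
  y <- c(2.0, 3.1, 1.2, 2.9, 3.5, 2.2, 1.0, 2.0, 4.1, 1.8)
  res <- correlation_test(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((10 - 2) / (1 - r^2))
  expect_equal(res$r, r, tolerance = 1e-12)
  expect_equal(res$t, tstat, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  # orthogonalised pairs: r = 0, t = 0, p = 1
  x0 <- c(-1, 1, -1, 1); y0 <- c(-1, -1, 1, 1)
  res0 <- correlation_test(x0, y0)
  expect_equal(res0$r, 0)
  expect_equal(res0$p_value, 1)
  # collinear pairs: r = 1, p ~ 0
  resc <- correlation_test(1:10, 2 * (1:10) + 3)
  expect_equal(resc$r, 1)
  expect_lt(resc$p_value, 1e-12)
  expect_error(correlation_test(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(correlation_test(1:2, 2:3), "3 complete pairs")
})

make_cv_population <- function(seed = 51, h2 = 0.6, n_markers = 400) {
  cfg <- sim_config(
    n_markers = n_markers,
    designs = list(factorial_design("4x6", 4, 6, n_me_males = 1,
                                    balanced_females = 3, extra_crosses = 3)),
    offspring_min = 8, offspring_mean = 14, offspring_max = 22,
    traits = list(trait_architecture("t", mean = 10, h2 = h2,
                                     range = c(-50, 70),
                                     cross_type_effect = -1)),
    years = c("Y1", "Y2"), dropout = 0, seed = seed)
  pop <- simulate_population(cfg)
  fl <- filter_markers(pop$dosages, min_maf = 0.02)
  list(pop = pop, grm = build_grm(fl$matrix))
}

test_that("LOO masking leaks nothing and matches an explicit refit", {
  cvp <- make_cv_population(seed = 52)
  pop <- cvp$pop
  spec <- model_spec("t", fixed = "year")
  fit <- fit_gblup(pop$records, spec, cvp$grm, pop$pedigree,
                   compute_pev = FALSE)
  res <- loo_predictive_ability(pop$records, spec, cvp$grm, pop$pedigree,
                                fit = fit)
  # explicit per-fold refit at the same fixed variance components
  vc <- list(sigma_a2 = fit$vc$sigma_a2, sigma_e2 = fit$vc$sigma_e2)
  for (id in sample(res$folds$id, 4)) {
    keep <- pop$records$id != id
    f2 <- fit_gblup(pop$records[keep, ], spec, cvp$grm, pop$pedigree,
                    vc = vc, compute_pev = FALSE)
    expect_equal(res$folds$gebv[res$folds$id == id], unname(f2$gebv[id]),
                 tolerance = 1e-8)
  }
  # mean observation is the unadjusted mean of the female's raw records
  id1 <- res$folds$id[1]
  expect_equal(res$folds$mean_obs[res$folds$id == id1],
               mean(pop$records$value[pop$records$id == id1]))
  # group n's sum to overall n
  expect_identical(sum(vapply(res$by_cross_type, `[[`, 0L, "n")),
                   res$overall$n)
  expect_true(abs(res$overall$r) <= 1)
})

test_that("predictive ability is high at high h2 and null under permutation", {
  cvp <- make_cv_population(seed = 53, h2 = 0.9)
  pop <- cvp$pop
  spec <- model_spec("t", fixed = "year")
  res <- loo_predictive_ability(pop$records, spec, cvp$grm, pop$pedigree)
  expect_gt(res$overall$r, 0.5)
  # permuting phenotypes across individuals destroys the signal
  rec <- pop$records
  ids <- unique(rec$id)
  set.seed(99)
  newid <- setNames(sample(ids), ids)
  rec$id <- unname(newid[rec$id])
  resp <- loo_predictive_ability(rec, spec, cvp$grm, pop$pedigree)
  expect_lt(abs(resp$overall$r), 0.25)
  expect_lt(resp$overall$r, res$overall$r)
})

test_that("degenerate folds are rejected", {
  fx <- random_fixture(q = 8, seed = 61)
  rec2 <- fx$records[fx$records$id %in% fx$ids[1:2], ]
  expect_error(loo_predictive_ability(rec2, model_spec("t", fixed = "year"),
                                      fx$grm, fx$ped),
               ">= 2 phenotyped|>= 3 phenotyped")
})

test_that("subpopulation schemes restrict training and are deterministic", {
  cvp <- make_cv_population(seed = 54)
  pop <- cvp$pop
  spec <- model_spec("t", fixed = "year")
  tot1 <- subpopulation_cv(pop$records, spec, cvp$grm, pop$pedigree, "total")
  tot2 <- loo_predictive_ability(pop$records, spec, cvp$grm, pop$pedigree)
  expect_equal(tot1$overall$r, tot2$overall$r, tolerance = 1e-12)
  aa <- subpopulation_cv(pop$records, spec, cvp$grm, pop$pedigree, "AAxAA")
  expect_true(all(aa$folds$cross_type == "AAxAA"))
  star1 <- subpopulation_cv(pop$records, spec, cvp$grm, pop$pedigree,
                            "AAxAA*", n_repeats = 3, seed = 7)
  star2 <- subpopulation_cv(pop$records, spec, cvp$grm, pop$pedigree,
                            "AAxAA*", n_repeats = 3, seed = 7)
  expect_identical(star1$r_values, star2$r_values)
  n_me <- length(unique(pop$records$id[
    pop$pedigree$cross_type[match(pop$records$id, pop$pedigree$id)] ==
      "AAxME"]))
  expect_identical(star1$n_per_draw, n_me)
})

test_that("parent accuracy reflects relationship to the training set", {
  cvp <- make_cv_population(seed = 55)
  pop <- cvp$pop
  ped <- pop$pedigree
  spec <- model_spec("t", fixed = "year")
  me_male <- ped$id[ped$species == "ME"][1]
  aa_male <- setdiff(ped$id[ped$sex == "M" & is.na(ped$mother)], me_male)[1]
  prof <- parent_accuracy_profile(
    pop$records, spec, cvp$grm, ped, parents = c(me_male, aa_male),
    schemes = list(total = "total", AAxAA = "AAxAA",
                   none = character(0)))
  # no records at all -> accuracy exactly 0
  expect_true(all(prof$accuracy[prof$scheme == "none"] == 0))
  acc <- function(p, s) prof$accuracy[prof$parent == p & prof$scheme == s]
  # the ME father loses information when training is intra-specific only
  expect_gt(acc(me_male, "total"), acc(me_male, "AAxAA"))
  expect_error(parent_accuracy_profile(pop$records, spec, cvp$grm, ped,
                                       parents = "ghost"),
               "absent from G")
})
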