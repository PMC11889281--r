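test_that("heritability and Henderson accuracy follow their closed forms", {
  expect_equal(heritability(list(sigma_a2 = 1, sigma_e2 = 1)), 0.5)
  expect_equal(heritability(list(sigma_a2 = 0, sigma_e2 = 3)), 0)
  expect_equal(heritability(list(sigma_a2 = 3, sigma_e2 = 1)), 0.75)
  expect_error(heritability(list(sigma_a2 = 0, sigma_e2 = 0)), "positive")
  expect_equal(henderson_accuracy(0, 2, 1), 1)
  expect_equal(henderson_accuracy(2, 2, 1), 0)
  expect_equal(henderson_accuracy(1, 2, 1), sqrt(0.5))
  expect_warning(acc <- henderson_accuracy(2.5, 2, 1), "clamped")
  expect_equal(acc, 0)
  expect_error(henderson_accuracy(1, 0, 1), "sigma_a2")
  expect_error(henderson_accuracy(-1, 1, 1), "non-negative")
})

test_that("REML/MME agree with the dense grid + inversion oracle", {
  # parameterised sweep over random small fixtures
  for (seed in c(1, 2, 3, 7, 11)) {
    fx <- random_fixture(q = 8 + (seed %% 3) * 4, seed = seed)
    spec <- model_spec("t", fixed = "year")
    fit <- fit_gblup(fx$records, spec, fx$grm, fx$ped)
    dp <- dense_pieces(fit, fx$grm)
    orc <- mme_oracle(dp$y, dp$X, dp$Z, dp$Gt)
    expect_equal(fit$vc$loglik, orc$loglik, tolerance = 1e-6)
    expect_equal(unname(fit$b), unname(orc$b), tolerance = 1e-6)
    expect_equal(unname(fit$gebv[dp$phen]), unname(orc$gebv),
                 tolerance = 1e-6)
    expect_equal(unname(fit$pev[dp$phen]), unname(orc$pev),
                 tolerance = 1e-6)
  }
})

test_that("pure-noise phenotypes drive sigma_a2 to the boundary", {
  set.seed(5)
  ids <- sprintf("i%02d", 1:40)
  G <- diag(40); dimnames(G) <- list(ids, ids)
  # two records per individual so the variance ratio is identifiable
  rec <- data.frame(id = rep(ids, 2), trait = "t",
                    year = rep(c("Y1", "Y2"), each = 40),
                    value = rnorm(80), stringsAsFactors = FALSE)
  ped <- data.frame(id = ids, mother = NA, father = NA, sex = "F",
                    species = "AA", cross_id = NA, cross_type = "founder",
                    stringsAsFactors = FALSE)
  fit <- fit_gblup(rec, model_spec("t", fixed = character(0)), G, ped,
                   compute_pev = FALSE)
  expect_true(fit$vc$boundary)
  expect_lt(fit$heritability, 0.01)
})

test_that("with G = I, GEBVs are ridge-shrunken residuals", {
  set.seed(6)
  ids <- sprintf("i%02d", 1:25)
  G <- diag(25); dimnames(G) <- list(ids, ids)
  y <- rnorm(25, 10, 2)
  rec <- data.frame(id = ids, trait = "t", year = "Y1", value = y,
                    stringsAsFactors = FALSE)
  ped <- data.frame(id = ids, mother = NA, father = NA, sex = "F",
                    species = "AA", cross_id = NA, cross_type = "founder",
                    stringsAsFactors = FALSE)
  shrink <- function(vc) {
    fit <- fit_gblup(rec, model_spec("t", fixed = character(0)), G, ped,
                     vc = vc, compute_pev = FALSE)
    fit$gebv[ids]
  }
  # closed form: a_i = (y_i - ybar-ish GLS mean) * sa2/(sa2+se2) with G=I,
  # one record each; check against the explicit ridge formula
  vc <- list(sigma_a2 = 2, sigma_e2 = 1)
  lam <- vc$sigma_e2 / vc$sigma_a2
  # GLS intercept with V = (sa2+se2)I is the plain mean
  expect_equal(unname(shrink(vc)), unname((y - mean(y)) / (1 + lam)),
               tolerance = 1e-6)
  # shrinkage toward zero increases with the noise ratio
  s1 <- shrink(list(sigma_a2 = 2, sigma_e2 = 0.5))
  s2 <- shrink(list(sigma_a2 = 2, sigma_e2 = 2))
  s3 <- shrink(list(sigma_a2 = 2, sigma_e2 = 8))
  expect_true(all(abs(s2) <= abs(s1) + 1e-12))
  expect_true(all(abs(s3) <= abs(s2) + 1e-12))
})

test_that("unphenotyped relatives are predicted through G", {
  pop <- small_population(seed = 41, n_markers = 600, dropout = 0)
  fl <- filter_markers(pop$dosages, min_maf = 0.02)
  grm <- build_grm(fl$matrix)
  spec <- model_spec("t", fixed = "year")
  fit <- fit_gblup(pop$records, spec, grm, pop$pedigree, compute_pev = FALSE)
  tv <- pop$phenotype_details$t$true_values
  tbv <- stats::setNames(tv$tbv, tv$id)
  males <- pop$pedigree$id[pop$pedigree$sex == "M" &
                             !is.na(pop$pedigree$mother)]
  expect_true(all(males %in% names(fit$gebv)))
  # predicted GEBVs of never-phenotyped males track their TBVs
  expect_gt(cor(fit$gebv[males], tbv[males]), 0.3)
})

test_that("aliased fixed-effect terms get df = 0, not silently dropped", {
  fx <- random_fixture(q = 10, seed = 9)
  # cross_type is constant ("founder" pedigree): its block is fully aliased
  spec <- model_spec("t", fixed = c("year", "cross_type"))
  fit <- fit_gblup(fx$records, spec, fx$grm, fx$ped)
  w <- wald_tests(fit)
  expect_identical(w$df[w$term == "cross_type"], 0L)
  expect_true(w$aliased[w$term == "cross_type"])
  expect_false(w$aliased[w$term == "year"])
  expect_error(model_spec("t", fixed = "year:cross_type"), "both main effects")
})

test_that("strong year effects are detected by the sequential Wald test", {
  set.seed(8)
  hits <- 0L
  for (r in 1:10) {
    fx <- random_fixture(q = 30, seed = 100 + r)
    rec <- fx$records
    rec$value <- rec$value + ifelse(rec$year == "Y2", 3, 0)  # ~3 sd shift
    fit <- fit_gblup(rec, model_spec("t", fixed = "year"), fx$grm, fx$ped,
                     compute_pev = FALSE)
    w <- wald_tests(fit)
    if (w$p_value[w$term == "year"] < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
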