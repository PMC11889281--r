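test_that("gamete distributions match exhaustive enumeration for all dosages", {
  for (alpha in c(0, 0.1, 1 / 6)) {
    for (d in 0:4) {
      expect_equal(unname(gamete_dosage_distribution(d, 4, alpha)),
                   enum_gamete_dist(d, 4, alpha), tolerance = 1e-12,
                   label = sprintf("d=%d alpha=%.3f", d, alpha))
    }
  }
  # hexaploid bivalent case against enumeration too
  for (d in 0:6)
    expect_equal(unname(gamete_dosage_distribution(d, 6, 0)),
                 enum_gamete_dist(d, 6, 0), tolerance = 1e-12)
  expect_equal(unname(gamete_dosage_distribution(0, 4, 0)), c(1, 0, 0))
  expect_equal(unname(gamete_dosage_distribution(2, 4, 0)), c(1, 4, 1) / 6)
  expect_equal(unname(gamete_dosage_distribution(2, 4, 0.1)), c(0.2, 0.6, 0.2))
  expect_error(gamete_dosage_distribution(5, 4), "0..4")
  expect_error(gamete_dosage_distribution(2, 4, 0.3), "1/6")
})

test_that("founder dosages are binomial in the species frequency", {
  # boundary frequencies are handled by direct binomial draws
  set.seed(1)
  expect_true(all(rbinom(100, 4, 0) == 0))
  fs <- sample_founder_dosages(c(AA = 10000), n_markers = 3, fst = 0,
                               base_freq_range = c(0.3, 0.300001), seed = 3)
  # mean dosage within 3 MC standard errors of m*p = 1.2
  se <- sqrt(4 * 0.3 * 0.7 / 10000)
  expect_true(all(abs(colMeans(unclass(fs$dosages)) - 1.2) < 3 * se))
  expect_true(all(unclass(fs$dosages) %in% 0:4))
  # column means / m estimate the realised species frequency
  fs2 <- sample_founder_dosages(c(AA = 5000, ME = 5000), n_markers = 5,
                                fst = 0.2, seed = 9)
  est <- colMeans(unclass(fs2$dosages)[fs2$species == "ME", ]) / 4
  se2 <- sqrt(fs2$freqs["ME", ] * (1 - fs2$freqs["ME", ]) / (4 * 5000))
  expect_true(all(abs(est - fs2$freqs["ME", ]) < 4 * se2))
  expect_error(sample_founder_dosages(c(AA = 0), 10), "at least one founder")
})

test_that("offspring dosages follow the gamete-distribution convolution", {
  mk <- function(d, n = 1) stats::setNames(rep(d, n), paste0("m", seq_len(n)))
  # fixed-allele boundary crosses
  off <- simulate_cross(mk(4, 5), mk(4, 5), 10, seed = 2)
  expect_true(all(unclass(off) == 4))
  off2 <- simulate_cross(mk(0, 5), mk(4, 5), 10, seed = 2)
  expect_true(all(unclass(off2) == 2))
  # convolution for a 2 x 2 cross: (1,4,1)/6 * (1,4,1)/6
  conv <- convolve(c(1, 4, 1) / 6, rev(c(1, 4, 1) / 6), type = "open")
  expect_equal(conv, c(1, 8, 18, 8, 1) / 36, tolerance = 1e-12)
  off3 <- simulate_cross(mk(2), mk(2), 20000, seed = 5)
  obs <- tabulate(unclass(off3)[, 1] + 1L, nbins = 5) / 20000
  se <- sqrt(conv * (1 - conv) / 20000)
  expect_true(all(abs(obs - conv) < 3.5 * se))
  gof <- chisq.test(tabulate(unclass(off3)[, 1] + 1L, nbins = 5), p = conv)
  expect_gt(gof$p.value, 0.001)
  expect_error(simulate_cross(mk(2, 3), mk(2, 2), 5), "marker set")
})

test_that("design builder realises the configured factorials", {
  cfg <- sim_config(n_markers = 10,
                    designs = list(factorial_design("2x13", 2, 13)),
                    offspring_min = 20, offspring_mean = 20,
                    offspring_max = 20, seed = 4)
  ped <- build_design(cfg)
  off <- ped[!is.na(ped$mother), ]
  expect_identical(length(unique(off$cross_id)), 26L)
  expect_identical(nrow(off), 520L)
  expect_true(all(table(off$cross_id) == 20))
  # study-shaped default: 55 crosses, 7x3 balanced block, two species
  ped2 <- build_design(sim_config(seed = 8))
  off2 <- ped2[!is.na(ped2$mother), ]
  expect_identical(length(unique(off2$cross_id)), 55L)
  expect_identical(length(unique(off2$cross_id[off2$cross_type == "AAxME"])), 7L)
  bal <- off2[off2$balanced_subset, ]
  expect_identical(length(unique(bal$cross_id)), 21L)
  expect_identical(length(unique(bal$mother)), 7L)
  expect_true(all(table(bal$mother, bal$father) > 0))
  sz <- table(off2$cross_id)
  expect_true(all(sz >= 2 & sz <= 80))
  expect_silent(validate_pedigree(ped2))
})

test_that("offspring-per-cross counts are calibrated to the study's range", {
  set.seed(10)
  # the configured distribution: min 2, max 80, mean 33.3
  sizes <- replicate(40, {
    ped <- build_design(sim_config(seed = sample.int(1e6, 1)))
    mean(table(ped$cross_id[!is.na(ped$mother)]))
  })
  expect_lt(abs(mean(sizes) - 33.3), 2)
})

test_that("phenotype simulator honours the additive model", {
  pop <- small_population(seed = 21, dropout = 0)
  ped <- pop$pedigree
  # exact records when h2 = 1 and all fixed effects are off
  arch <- trait_architecture("pure", mean = 5, h2 = 1, range = c(-100, 100),
                             year_sd = 0, cross_type_effect = 0)
  sim <- simulate_phenotypes(pop$dosages, ped, arch, years = "Y1", seed = 31)
  tbv <- stats::setNames(sim$true_values$tbv, sim$true_values$id)
  expect_equal(sim$records$value, unname(5 + tbv[sim$records$id]),
               tolerance = 1e-10)
  # records exist only for female offspring; TBVs for everyone
  expect_true(all(sim$records$id %in% ped$id[ped$sex == "F" & !is.na(ped$mother)]))
  expect_setequal(sim$true_values$id, ped$id)
  # variance-ratio recovery at h2 = 0.5 on a larger set
  cfg <- sim_config(n_markers = 300, seed = 77,
                    designs = list(factorial_design("4x8", 4, 8)),
                    offspring_min = 50, offspring_mean = 63, offspring_max = 76,
                    traits = list(trait_architecture("vr", mean = 0, h2 = 0.5,
                                                     range = c(-1e6, 1e6),
                                                     year_sd = 0)),
                    years = "Y1", dropout = 0)
  pop2 <- simulate_population(cfg)
  d <- pop2$phenotype_details$vr
  ratio <- d$var_tbv / stats::var(d$records$value)
  expect_lt(abs(ratio - 0.5), 0.05)
  # zero-variance TBV with h2 < 1 is an error
  const <- dosage_matrix(matrix(2, nrow(ped), 3,
                                dimnames = list(ped$id, paste0("m", 1:3))))
  archc <- trait_architecture("c", mean = 1, h2 = 0.4, range = c(0, 2))
  expect_error(simulate_phenotypes(const, ped, archc, years = "Y1"),
               "zero.variance TBV|zero TBV variance")
})

test_that("dropout removes whole females and master seed is reproducible", {
  cfg <- sim_config(n_markers = 50, seed = 99, dropout = 0.3,
                    designs = list(factorial_design("3x4", 3, 4)),
                    offspring_min = 10, offspring_mean = 14, offspring_max = 20)
  pop <- simulate_population(cfg)
  females <- pop$pedigree$id[pop$pedigree$sex == "F" &
                               !is.na(pop$pedigree$mother)]
  for (tr in unique(pop$records$trait)) {
    ph <- unique(pop$records$id[pop$records$trait == tr])
    expect_true(length(ph) < length(females))   # some dropped
    expect_true(all(table(pop$records$id[pop$records$trait == tr]) >= 1))
  }
  pop2 <- simulate_population(cfg)
  expect_identical(pop$records, pop2$records)
  expect_identical(unclass(pop$dosages), unclass(pop2$dosages))
})

test_that("gene-dropping reproduces pedigree expectations", {
  ped <- data.frame(
    id = c("F1", "F2", "M1", "M2", "o1", "o2", "o3", "o4"),
    mother = c(NA, NA, NA, NA, "F1", "F1", "F1", "F2"),
    father = c(NA, NA, NA, NA, "M1", "M1", "M2", "M2"),
    sex = c("F", "F", "M", "M", "F", "M", "F", "F"),
    species = "AA", cross_id = c(NA, NA, NA, NA, "C1", "C1", "C2", "C3"),
    cross_type = c(rep("founder", 4), rep("AAxAA", 4)),
    stringsAsFactors = FALSE)
  A <- gene_drop_relationship(ped, n_reps = 4000, seed = 6)
  expect_equal(A, t(A))
  expect_equal(unname(diag(A)[1:4]), rep(1, 4), tolerance = 1e-12)
  expect_equal(A["F1", "M1"], 0, tolerance = 1e-12)   # unrelated founders
  # tetraploid expectations: parent-offspring 1/2, full-sib 1/2, half-sib 1/4
  expect_equal(A["F1", "o1"], 0.5, tolerance = 0.03)
  expect_equal(A["o1", "o2"], 0.5, tolerance = 0.03)
  expect_equal(A["o1", "o3"], 0.25, tolerance = 0.03)
  expect_gt(mean(c(A["o1", "o2"])), mean(c(A["o1", "o3"])))
  # PSD up to MC noise
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -0.02)
})
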