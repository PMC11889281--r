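#' True breeding values from marker effects
#'
#' `TBV_i = sum_j alpha_j * (m_ij - ploidy * p_j)` with `p_j` the founder
#' allele frequencies, so the founder-population mean TBV is
#' approximately zero.
#'
#' @param dosages A complete [dosage_matrix()].
#' @param effects Per-marker additive effect vector.
#' @param freqs Allele frequencies used for centering.
#' @return Named numeric vector of TBVs.
#' @export
true_breeding_values <- function(dosages, effects, freqs) {
  stopifnot(ncol(dosages) == length(effects), length(freqs) == length(effects))
  Z <- sweep(unclass(dosages), 2L, ploidy(dosages) * freqs)
  drop(Z %*% effects)
}

#' Simulate multi-year additive phenotypes on female offspring
#'
#' Generates long-format records following the additive model
#' `y = mu + year + cross_type + year:cross_type + TBV + e`,
#' `e ~ N(0, sigma_e^2)`, for female offspring only (the traits are
#' female-expressed). Per-marker effects are drawn zero-mean normal and
#' rescaled so the realised TBV variance among female offspring equals
#' the architecture's `genetic_var`; the residual variance derives from
#' the target heritability as `var(TBV) * (1 - h2) / h2`, computed on
#' the phenotyped females. Records are clipped to the architecture's
#' trait range. With probability `dropout` a female loses all her
#' records for the trait (emulating the exclusion of zero-score vines).
#'
#' @param dosages Complete [dosage_matrix()] covering all pedigree ids.
#' @param ped Pedigree from [build_design()].
#' @param arch A [trait_architecture()].
#' @param years Character vector of candidate year labels (the
#'   architecture may restrict to a subset).
#' @param seed RNG seed.
#' @param founder_freqs Optional allele-frequency vector for TBV
#'   centering; default: frequencies of the pedigree founders.
#' @param dropout Per-female dropout probability.
#' @return List with `records` (id, trait, year, value), `true_values`
#'   (id, trait, tbv for every individual), `expected` (per-record value
#'   before noise), `effects`, `sigma_e2`, `var_tbv`, and the realised
#'   fixed effects (`year_effects`, `cross_type_effect`,
#'   `interaction_effects`).
#' @export
simulate_phenotypes <- function(dosages, ped, arch, years, seed = 1L,
                                founder_freqs = NULL, dropout = 0) {
  stopifnot(inherits(arch, "trait_architecture"))
  m <- ploidy(dosages)
  if (!all(ped$id %in% rownames(dosages)))
    stop2("dosage matrix lacks pedigree id(s): ",
          paste(utils::head(setdiff(ped$id, rownames(dosages)), 3), collapse = ", "))
  if (!is.null(arch$years)) years <- intersect(years, arch$years)
  if (!length(years)) stop2("trait '", arch$name, "' has no recording years")
  females <- ped$id[ped$sex == "F" & !is.na(ped$mother)]
  if (!length(females)) stop2("design contains no female offspring to phenotype")
  if (is.null(founder_freqs)) {
    fnd <- ped$id[is.na(ped$mother)]
    if (!length(fnd)) fnd <- ped$id
    founder_freqs <- colMeans(unclass(dosages)[fnd, , drop = FALSE]) / m
  }
  with_seed(seed, {
    eff <- stats::rnorm(ncol(dosages))
    tbv <- true_breeding_values(dosages[ped$id, , drop = FALSE], eff,
                                founder_freqs)
    off <- ped$id[!is.na(ped$mother)]
    v <- stats::var(tbv[off])
    if (v <= 0) {
      if (arch$h2 < 1) stop2("zero-variance TBV with h2 < 1 for trait '",
                             arch$name, "'")
    } else {
      sc <- sqrt(arch$genetic_var / v)
      eff <- eff * sc
      tbv <- tbv * sc
    }
    keep <- females[stats::runif(length(females)) >= dropout]
    if (!length(keep)) stop2("all phenotyped females dropped out")
    v_tbv <- stats::var(tbv[keep])
    if (v_tbv <= 0 && arch$h2 < 1)
      stop2("zero TBV variance among phenotyped females with h2 < 1")
    sigma_e2 <- if (arch$h2 >= 1) 0 else v_tbv * (1 - arch$h2) / arch$h2
    ye <- stats::setNames(stats::rnorm(length(years), 0, arch$year_sd), years)
    ie <- stats::setNames(stats::rnorm(length(years), 0, arch$interaction_sd),
                          years)
    rec <- expand.grid(id = keep, year = years, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    ct <- ped$cross_type[match(rec$id, ped$id)]
    inter <- ct == "AAxME"
    mu_rec <- arch$mean + ye[rec$year] + arch$cross_type_effect * inter +
      ie[rec$year] * inter + tbv[rec$id]
    val <- mu_rec + stats::rnorm(nrow(rec), 0, sqrt(sigma_e2))
    val <- pmin(arch$range[2], pmax(arch$range[1], val))
    records <- data.frame(id = rec$id, trait = arch$name, year = rec$year,
                          value = unname(val), stringsAsFactors = FALSE)
    records <- records[order(records$id, records$year), ]
    rownames(records) <- NULL
    list(records = records,
         true_values = data.frame(id = ped$id, trait = arch$name,
                                  tbv = unname(tbv[ped$id]),
                                  stringsAsFactors = FALSE),
         expected = data.frame(id = rec$id, trait = arch$name,
                               year = rec$year, expected = unname(mu_rec),
                               stringsAsFactors = FALSE),
         effects = eff, sigma_e2 = sigma_e2, var_tbv = v_tbv,
         year_effects = ye, cross_type_effect = arch$cross_type_effect,
         interaction_effects = ie)
  })
}

#' Simulate a complete breeding population
#'
#' Runs the full generator: founder sampling, design construction,
#' polysomic meiosis for every cross, and phenotype simulation for every
#' configured trait. Stage sub-seeds derive from the configuration's
#' master seed, so individual stages are independently reproducible.
#'
#' @param config A [sim_config()].
#' @return List with `dosages` (founders + offspring), `pedigree`,
#'   `records` (all traits stacked), `true_values`, `founder_freqs`
#'   (species x markers), `phenotype_details` (per-trait simulator
#'   output), and `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ped <- build_design(config)
  fnd_rows <- ped[is.na(ped$mother), ]
  counts <- table(factor(fnd_rows$species, levels = unique(fnd_rows$species)))
  fnd <- sample_founder_dosages(
    stats::setNames(as.integer(counts), names(counts)),
    n_markers = config$n_markers, ploidy = config$ploidy, fst = config$fst,
    base_freq_range = config$base_freq_range,
    seed = derive_seed(config$seed, "founders"),
    ids = unlist(lapply(names(counts), function(s)
      fnd_rows$id[fnd_rows$species == s]), use.names = FALSE))
  dos <- simulate_offspring_dosages(fnd$dosages, ped, config$ploidy,
                                    config$double_reduction,
                                    derive_seed(config$seed, "meiosis"))
  dos <- dos[ped$id, , drop = FALSE]
  details <- list(); recs <- list(); tvs <- list()
  for (arch in config$traits) {
    sim <- simulate_phenotypes(dos, ped, arch, config$years,
                               seed = derive_seed(config$seed,
                                                  paste0("trait:", arch$name)),
                               dropout = config$dropout)
    details[[arch$name]] <- sim
    recs[[arch$name]] <- sim$records
    tvs[[arch$name]] <- sim$true_values
  }
  records <- do.call(rbind, recs); rownames(records) <- NULL
  true_values <- do.call(rbind, tvs); rownames(true_values) <- NULL
  validate_phenotypes(records, ped)
  list(dosages = dos, pedigree = ped, records = records,
       true_values = true_values, founder_freqs = fnd$freqs,
       phenotype_details = details, config = config)
}
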