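#' Trait architecture for the phenotype simulator
#'
#' Describes one additive trait: its overall mean, target narrow-sense
#' heritability, genetic variance, fixed-effect generators and clipping
#' range. Per-marker additive effects are drawn i.i.d. normal and then
#' rescaled so that the realised true-breeding-value (TBV) variance in
#' the simulated offspring equals `genetic_var`; the residual variance is
#' derived from the target heritability as
#' `sigma_e^2 = var(TBV) * (1 - h2) / h2`.
#'
#' @param name Trait name.
#' @param mean Overall population mean (intercept), trait units.
#' @param h2 Target narrow-sense heritability, in (0, 1].
#' @param range Length-2 numeric clipping range for simulated records.
#' @param genetic_var Target additive variance; default `((range width)/10)^2`.
#' @param year_sd Standard deviation of the fixed year effects (drawn
#'   once per year, zero-mean normal); default `0.4 * sqrt(genetic_var)`.
#' @param cross_type_effect Additive shift applied to inter-specific
#'   (AAxME) offspring records, trait units.
#' @param interaction_sd Standard deviation of year-by-cross-type
#'   interaction effects (default 0, i.e. no interaction).
#' @param years Optional subset of the configuration's year labels over
#'   which this trait is recorded; `NULL` means all years.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(name, mean, h2, range,
                               genetic_var = ((range[2] - range[1]) / 10)^2,
                               year_sd = 0.4 * sqrt(genetic_var),
                               cross_type_effect = 0,
                               interaction_sd = 0,
                               years = NULL) {
  stopifnot(is.character(name), length(range) == 2L, all(is.finite(range)),
            range[1] < range[2])
  if (h2 <= 0 || h2 > 1) stop2("h2 must lie in (0, 1], got ", h2)
  if (genetic_var <= 0) stop2("genetic_var must be positive")
  structure(list(name = name, mean = mean, h2 = h2, range = range,
                 genetic_var = genetic_var, year_sd = year_sd,
                 cross_type_effect = cross_type_effect,
                 interaction_sd = interaction_sd, years = years),
            class = "trait_architecture")
}

# Trait set emulating a kiwiberry-type breeding programme: a 0.5-9 scored
# fruit load (treated as continuous, as the downstream LMM does), fruit
# weight (g), dry-matter percentage and soluble-solids content (degrees
# Brix), with means/ranges typical of such programmes, inter-specific
# crosses shifted downwards, and moderate-to-high additive heritability.
default_traits <- function() {
  list(
    trait_architecture("fruit_load", mean = 4.4, h2 = 0.60,
                       range = c(0.5, 9.0), cross_type_effect = -0.3,
                       years = c("Y1", "Y2")),
    trait_architecture("fruit_weight", mean = 8.0, h2 = 0.55,
                       range = c(1.0, 17.3), cross_type_effect = -1.9),
    trait_architecture("dry_matter", mean = 20.7, h2 = 0.45,
                       range = c(12.0, 29.3), cross_type_effect = -3.1),
    trait_architecture("soluble_solids", mean = 16.1, h2 = 0.50,
                       range = c(9.1, 22.4), cross_type_effect = -2.3,
                       years = c("Y1", "Y2"))
  )
}

#' Factorial crossing-design specification
#'
#' One incomplete factorial of `n_females` mothers by `n_males` fathers.
#' The first `n_me_males` fathers belong to the second species ("ME");
#' all mothers and remaining fathers are species "AA". The first
#' `balanced_females` mothers are crossed with every father (the
#' balanced subset); each remaining mother is crossed with a random
#' draw of the AA fathers so that the factorial realises
#' `extra_crosses` additional intra-specific crosses.
#'
#' @param name Factorial label.
#' @param n_females,n_males Parent pool sizes.
#' @param n_me_males Number of fathers from the second species.
#' @param balanced_females Mothers crossed with all fathers.
#' @param extra_crosses Crosses realised outside the balanced block.
#' @return A `factorial_design` specification.
#' @export
factorial_design <- function(name, n_females, n_males, n_me_males = 0L,
                             balanced_females = n_females,
                             extra_crosses = 0L) {
  stopifnot(n_females >= 1, n_males >= 1, n_me_males >= 0,
            n_me_males <= n_males, balanced_females <= n_females)
  spare <- (n_females - balanced_females) * (n_males - n_me_males)
  if (extra_crosses > spare)
    stop2("factorial '", name, "': ", extra_crosses,
          " extra crosses requested but only ", spare, " combinations remain")
  structure(list(name = name, n_females = as.integer(n_females),
                 n_males = as.integer(n_males),
                 n_me_males = as.integer(n_me_males),
                 balanced_females = as.integer(balanced_females),
                 extra_crosses = as.integer(extra_crosses)),
            class = "factorial_design")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-population generator. The default
#' configuration emulates a two-species kiwiberry breeding programme:
#' two incomplete factorials (2 x 13, all intra-specific, and 13 x 3
#' with one inter-specific father and a balanced 7 x 3 block), 55
#' realised crosses, offspring-per-cross between 2 and 80 with mean
#' 33.3, a 7259-marker post-QC dosage panel, two founder species pools
#' with low differentiation (Fst = 0.05), tetraploid polysomic
#' inheritance without double reduction, and female-only phenotypes
#' over up to three years.
#'
#' @param n_markers Number of unlinked biallelic markers.
#' @param ploidy Even ploidy (default 4, autotetraploid).
#' @param designs List of [factorial_design()] specifications.
#' @param offspring_min,offspring_mean,offspring_max Offspring-per-cross
#'   distribution (discretised Beta rescaled to \[min, max\] with the
#'   stated mean).
#' @param fst Balding-Nichols differentiation between the two founder
#'   species pools, in \[0, 1).
#' @param base_freq_range Range of the uniform ancestral allele
#'   frequencies.
#' @param double_reduction Double-reduction rate `alpha` in \[0, 1/6\].
#' @param traits List of [trait_architecture()] objects.
#' @param years Character vector of year labels.
#' @param dropout Per-(female, trait) probability that all her records
#'   for the trait are discarded (emulates excluding zero-score vines).
#' @param seed Master seed; stage sub-seeds derive from it via
#'   [derive_seed()].
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_markers = 7259L,
                       ploidy = 4L,
                       designs = list(
                         factorial_design("2x13", 2, 13),
                         factorial_design("13x3", 13, 3, n_me_males = 1L,
                                          balanced_females = 7L,
                                          extra_crosses = 8L)),
                       offspring_min = 2L,
                       offspring_mean = 33.3,
                       offspring_max = 80L,
                       fst = 0.05,
                       base_freq_range = c(0.1, 0.9),
                       double_reduction = 0,
                       traits = default_traits(),
                       years = c("Y1", "Y2", "Y3"),
                       dropout = 0.05,
                       seed = 1L) {
  ploidy <- as.integer(ploidy)
  if (ploidy < 2L || ploidy %% 2L != 0L) stop2("ploidy must be even and >= 2")
  if (n_markers < 1L) stop2("n_markers must be >= 1")
  if (double_reduction < 0 || double_reduction > 1 / 6)
    stop2("double_reduction must lie in [0, 1/6]")
  if (fst < 0 || fst >= 1) stop2("fst must lie in [0, 1)")
  if (offspring_min < 1L || offspring_min > offspring_mean ||
      offspring_mean > offspring_max)
    stop2("need 1 <= offspring_min <= offspring_mean <= offspring_max")
  if (dropout < 0 || dropout >= 1) stop2("dropout must lie in [0, 1)")
  stopifnot(length(years) >= 1L)
  for (d in designs) stopifnot(inherits(d, "factorial_design"))
  for (tr in traits) stopifnot(inherits(tr, "trait_architecture"))
  structure(list(n_markers = as.integer(n_markers), ploidy = ploidy,
                 designs = designs,
                 offspring_min = as.integer(offspring_min),
                 offspring_mean = offspring_mean,
                 offspring_max = as.integer(offspring_max),
                 fst = fst, base_freq_range = base_freq_range,
                 double_reduction = double_reduction,
                 traits = traits, years = as.character(years),
                 dropout = dropout, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_markers, "markers, ploidy", x$ploidy, "\n")
  for (d in x$designs)
    cat("  factorial", d$name, ":", d$n_females, "x", d$n_males,
        if (d$n_me_males) paste0("(", d$n_me_males, " ME male)") else "", "\n")
  cat("  offspring/cross:", x$offspring_min, "-", x$offspring_max,
      "mean", x$offspring_mean, "; Fst", x$fst,
      "; alpha", x$double_reduction, "\n")
  cat("  traits:", paste(vapply(x$traits, `[[`, "", "name"), collapse = ", "),
      "; years:", paste(x$years, collapse = ","),
      "; dropout", x$dropout, "; seed", x$seed, "\n")
  invisible(x)
}
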