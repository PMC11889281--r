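# Draw offspring-per-cross counts: a Beta variate rescaled to
# [min, max] and rounded, with the Beta mean chosen so the expected
# count equals the configured mean. Concentration 4 gives the wide
# spread (a handful to dozens of seedlings per cross) typical of
# factorial seedling trials.
sample_cross_sizes <- function(n, min, mean, max, conc = 4) {
  if (min == max) return(rep(min, n))
  mu <- (mean - min) / (max - min)
  x <- stats::rbeta(n, mu * conc, (1 - mu) * conc)
  pmin(max, pmax(min, as.integer(round(min + x * (max - min)))))
}

#' Build the crossing-design pedigree
#'
#' Instantiates the configured factorials as a pedigree table: founder
#' rows for every parent (mothers "F..", fathers "M..", the configured
#' number of fathers belonging to species "ME"), then one block of
#' offspring per realised cross. Offspring sex is Bernoulli(0.5),
#' offspring-per-cross counts follow the configured distribution, and
#' `cross_type` derives from the parental species (AAxAA when both
#' parents are species AA, AAxME otherwise). Crosses of the balanced
#' block of the factorial are flagged `balanced_subset`.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to the design sub-stream of the
#'   config's master seed.
#' @return A validated pedigree data.frame (see [validate_pedigree()]).
#' @export
build_design <- function(config, seed = derive_seed(config$seed, "design")) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    founders <- list(); offspring <- list(); cross_no <- 0L
    for (d in config$designs) {
      fem <- sprintf("%s_F%02d", d$name, seq_len(d$n_females))
      mal <- sprintf("%s_M%02d", d$name, seq_len(d$n_males))
      msp <- c(rep("ME", d$n_me_males), rep("AA", d$n_males - d$n_me_males))
      founders[[d$name]] <- data.frame(
        id = c(fem, mal), mother = NA_character_, father = NA_character_,
        sex = rep(c("F", "M"), c(d$n_females, d$n_males)),
        species = c(rep("AA", d$n_females), msp),
        cross_id = NA_character_, cross_type = "founder",
        factorial = d$name, balanced_subset = FALSE,
        stringsAsFactors = FALSE)
      # realised crosses: balanced block, then random extra combinations
      pairs <- expand.grid(f = fem[seq_len(d$balanced_females)], m = mal,
                           stringsAsFactors = FALSE)
      pairs$balanced <- d$balanced_females < d$n_females
      if (d$extra_crosses > 0L) {
        rest <- expand.grid(f = fem[-seq_len(d$balanced_females)],
                            m = mal[msp == "AA"], stringsAsFactors = FALSE)
        take <- rest[sample.int(nrow(rest), d$extra_crosses), , drop = FALSE]
        take$balanced <- FALSE
        pairs <- rbind(pairs, take)
      }
      sizes <- sample_cross_sizes(nrow(pairs), config$offspring_min,
                                  config$offspring_mean, config$offspring_max)
      for (k in seq_len(nrow(pairs))) {
        cross_no <- cross_no + 1L
        cid <- sprintf("C%02d", cross_no)
        n <- sizes[k]
        fsp <- msp[match(pairs$m[k], mal)]
        offspring[[cid]] <- data.frame(
          id = sprintf("%s_%03d", cid, seq_len(n)),
          mother = pairs$f[k], father = pairs$m[k],
          sex = c("F", "M")[stats::rbinom(n, 1, 0.5) + 1L],
          species = if (fsp == "AA") "AA" else "AA/ME",
          cross_id = cid,
          cross_type = if (fsp == "AA") "AAxAA" else "AAxME",
          factorial = d$name, balanced_subset = pairs$balanced[k],
          stringsAsFactors = FALSE)
      }
    }
    ped <- do.call(rbind, c(founders, offspring))
    rownames(ped) <- NULL
    validate_pedigree(ped)
    ped
  })
}

#' Extract the balanced-subset individuals of a factorial
#'
#' @param ped Pedigree from [build_design()].
#' @return Character vector of offspring ids belonging to crosses of a
#'   balanced factorial block.
#' @export
balanced_subset_ids <- function(ped) {
  ped$id[!is.na(ped$mother) & ped$balanced_subset]
}
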