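#' Sample founder dosages under polysomic Hardy-Weinberg equilibrium
#'
#' Ancestral allele frequencies are drawn uniformly on
#' `base_freq_range`; each species pool then receives its own
#' frequencies from a Balding-Nichols draw around the ancestral value,
#' `p_s,j ~ Beta(p0 * (1 - Fst) / Fst, (1 - p0) * (1 - Fst) / Fst)`
#' (for `Fst = 0` the pools share the ancestral frequencies exactly).
#' Founder dosages are then `Binomial(ploidy, p_s,j)`, the polysomic
#' Hardy-Weinberg dosage distribution, so column means divided by the
#' ploidy estimate the species frequencies.
#'
#' @param n_per_species Named integer vector, individuals per species,
#'   e.g. `c(AA = 20, ME = 5)`.
#' @param n_markers Number of markers.
#' @param ploidy Even ploidy.
#' @param fst Differentiation parameter in \[0, 1).
#' @param base_freq_range Range of ancestral frequencies.
#' @param seed RNG seed.
#' @param ids Optional character vector of founder ids (recycled over
#'   species in order); default `"<species><k>"`.
#' @return List with `dosages` (a [dosage_matrix()]), `freqs` (species x
#'   markers matrix of realised frequencies), `base_freq`, and `species`
#'   (per-individual species labels).
#' @export
sample_founder_dosages <- function(n_per_species, n_markers, ploidy = 4L,
                                   fst = 0.05, base_freq_range = c(0.1, 0.9),
                                   seed = 1L, ids = NULL) {
  if (is.null(names(n_per_species)) || any(n_per_species < 0))
    stop2("n_per_species must be a named non-negative integer vector")
  if (sum(n_per_species) < 1L) stop2("at least one founder must be requested")
  if (n_markers < 1L) stop2("n_markers must be >= 1")
  if (diff(base_freq_range) <= 0 || base_freq_range[1] <= 0 ||
      base_freq_range[2] >= 1)
    stop2("base_freq_range must be an increasing interval inside (0, 1)")
  with_seed(seed, {
    p0 <- stats::runif(n_markers, base_freq_range[1], base_freq_range[2])
    sp <- names(n_per_species)
    freqs <- matrix(NA_real_, length(sp), n_markers,
                    dimnames = list(sp, paste0("m", seq_len(n_markers))))
    for (s in sp) {
      if (fst > 0) {
        a <- p0 * (1 - fst) / fst
        b <- (1 - p0) * (1 - fst) / fst
        ps <- stats::rbeta(n_markers, a, b)
      } else ps <- p0
      freqs[s, ] <- pmin(pmax(ps, 1e-3), 1 - 1e-3)
    }
    ntot <- sum(n_per_species)
    species <- rep(sp, n_per_species)
    M <- matrix(0L, ntot, n_markers)
    row <- 1L
    for (s in sp) {
      ns <- n_per_species[[s]]
      if (ns == 0L) next
      M[row:(row + ns - 1L), ] <- matrix(
        stats::rbinom(ns * n_markers, ploidy, rep(freqs[s, ], each = ns)),
        ns, n_markers)
      row <- row + ns
    }
    if (is.null(ids))
      ids <- unlist(lapply(sp, function(s)
        sprintf("%s%02d", s, seq_len(n_per_species[[s]]))), use.names = FALSE)
    if (length(ids) != ntot) stop2("ids length does not match founder count")
    rownames(M) <- ids
    colnames(M) <- colnames(freqs)
    list(dosages = dosage_matrix(M, ploidy = ploidy), freqs = freqs,
         base_freq = p0, species = stats::setNames(species, ids))
  })
}
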