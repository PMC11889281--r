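#' Gamete dosage distribution under polysomic meiosis
#'
#' For a parent carrying `d` copies of the alternate allele among `m`
#' homologs, random bivalent pairing transmits a gamete of `m/2`
#' chromosomes whose alternate-allele count is hypergeometric:
#' `P(k) = choose(d, k) * choose(m - d, m/2 - k) / choose(m, m/2)`.
#' Double reduction is modelled as a two-component mixture: with
#' probability `alpha` the gamete instead carries two copies of one
#' uniformly chosen homolog, contributing dosage `0` or `2` with
#' probabilities `1 - d/m` and `d/m` (supported for ploidy 4, where a
#' gamete holds two chromosomes).
#'
#' @param d Parental dosage, integer in `0..ploidy`.
#' @param ploidy Even ploidy.
#' @param alpha Double-reduction rate in \[0, 1/6\].
#' @return Numeric probability vector over gamete dosages
#'   `0..ploidy/2` (sums to 1).
#' @export
#' @examples
#' gamete_dosage_distribution(2, 4, 0)    # (1/6, 4/6, 1/6)
#' gamete_dosage_distribution(2, 4, 0.1)  # (0.2, 0.6, 0.2)
gamete_dosage_distribution <- function(d, ploidy = 4L, alpha = 0) {
  if (length(d) != 1L || is.na(d) || d < 0 || d > ploidy || d != round(d))
    stop2("parental dosage must be a single integer in 0..", ploidy)
  if (alpha < 0 || alpha > 1 / 6)
    stop2("double-reduction rate must lie in [0, 1/6], got ", alpha)
  half <- ploidy %/% 2L
  k <- 0:half
  pr <- stats::dhyper(k, d, ploidy - d, half)
  if (alpha > 0) {
    if (ploidy != 4L)
      stop2("double reduction is modelled for ploidy 4 only")
    dr <- c(1 - d / ploidy, 0, d / ploidy)
    pr <- (1 - alpha) * pr + alpha * dr
  }
  stats::setNames(pr, k)
}

# Vectorised gamete sampling: D is an n x p matrix whose row r gives, per
# marker, the dosage of the parent of offspring r. Returns n x p gamete
# dosages. Uses the cumulative gamete distribution indexed by parental
# dosage, one uniform draw per cell.
sample_gametes <- function(D, ploidy, alpha) {
  half <- ploidy %/% 2L
  cum <- t(vapply(0:ploidy, function(d)
    cumsum(gamete_dosage_distribution(d, ploidy, alpha)),
    numeric(half + 1L)))
  u <- matrix(stats::runif(length(D)), nrow(D), ncol(D))
  g <- matrix(0L, nrow(D), ncol(D))
  for (k in seq_len(half))                      # count thresholds passed
    g <- g + (u > matrix(cum[D + 1L, k], nrow(D), ncol(D)))
  g
}

#' Simulate offspring dosages for one cross
#'
#' Per marker, each offspring receives an independently sampled maternal
#' and paternal gamete (markers unlinked); its dosage is the sum of the
#' two gamete dosages.
#'
#' @param mother,father Named numeric dosage vectors over the same
#'   marker set.
#' @param n_offspring Number of offspring to draw (>= 1).
#' @param ploidy Even ploidy.
#' @param alpha Double-reduction rate.
#' @param seed RNG seed.
#' @param ids Optional offspring ids.
#' @return A [dosage_matrix()] of `n_offspring` rows.
#' @export
simulate_cross <- function(mother, father, n_offspring, ploidy = 4L,
                           alpha = 0, seed = 1L, ids = NULL) {
  if (n_offspring < 1L) stop2("n_offspring must be >= 1")
  if (length(mother) != length(father) ||
      (!is.null(names(mother)) && !is.null(names(father)) &&
       !identical(names(mother), names(father))))
    stop2("mother and father dosage vectors must share one marker set")
  p <- length(mother)
  with_seed(seed, {
    Dm <- matrix(as.integer(mother), n_offspring, p, byrow = TRUE)
    Df <- matrix(as.integer(father), n_offspring, p, byrow = TRUE)
    off <- sample_gametes(Dm, ploidy, alpha) + sample_gametes(Df, ploidy, alpha)
    if (is.null(ids)) ids <- sprintf("off%03d", seq_len(n_offspring))
    rownames(off) <- ids
    colnames(off) <- if (!is.null(names(mother))) names(mother) else
      paste0("m", seq_len(p))
    dosage_matrix(off, ploidy = ploidy)
  })
}

# Simulate dosages for every offspring in a pedigree given founder rows.
# Offspring of the same cross are drawn together (vectorised); crosses
# get independent sub-seeds so the draw is order-stable.
simulate_offspring_dosages <- function(founders, ped, ploidy, alpha, seed) {
  off <- ped[!is.na(ped$mother), , drop = FALSE]
  if (!nrow(off)) return(founders)
  p <- ncol(founders)
  out <- matrix(0L, nrow(off), p,
                dimnames = list(off$id, colnames(founders)))
  for (cr in unique(off$cross_id)) {
    rows <- which(off$cross_id == cr)
    mo <- unclass(founders)[off$mother[rows[1]], ]
    fa <- unclass(founders)[off$father[rows[1]], ]
    kid <- simulate_cross(mo, fa, length(rows), ploidy = ploidy,
                          alpha = alpha,
                          seed = derive_seed(seed, paste0("cross:", cr)),
                          ids = off$id[rows])
    out[rows, ] <- unclass(kid)
  }
  dosage_matrix(rbind(unclass(founders), out), ploidy = ploidy)
}
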