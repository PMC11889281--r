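#' Gene-dropping expected additive-relationship matrix
#'
#' Monte-Carlo oracle for the realised relationship matrix: founders
#' receive unique homolog labels (assumed unrelated and non-inbred),
#' labels are dropped through the pedigree under the same gamete model
#' as the dosage simulator (bivalent pairing; with probability `alpha` a
#' gamete carries one homolog twice), and identity-by-descent sharing is
#' averaged over `n_reps` independent loci. The coancestry
#' `f_ij = P(random homolog of i IBD to random homolog of j)` (sampling
#' with replacement) is scaled by the ploidy, `A = ploidy * f`, so a
#' non-inbred founder has self-relationship 1 and, at ploidy 4 without
#' double reduction, parent-offspring pairs converge to 0.5, full sibs
#' to 0.5 and half sibs to 0.25 - the same scale as the dosage-based
#' genomic relationship matrix.
#'
#' @param ped Pedigree table (ancestor-ordered; see
#'   [validate_pedigree()]).
#' @param ploidy Even ploidy.
#' @param alpha Double-reduction rate.
#' @param n_reps Number of independent loci dropped (>= 100 for a
#'   usable oracle).
#' @param seed RNG seed.
#' @return Symmetric matrix with pedigree ids as dimnames.
#' @export
gene_drop_relationship <- function(ped, ploidy = 4L, alpha = 0,
                                   n_reps = 200L, seed = 1L) {
  validate_pedigree(ped)
  if (n_reps < 1L) stop2("n_reps must be >= 1")
  n <- nrow(ped)
  half <- ploidy %/% 2L
  mom <- match(ped$mother, ped$id)
  dad <- match(ped$father, ped$id)
  fnd <- which(is.na(mom))
  nlab <- length(fnd) * ploidy
  acc <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      L <- matrix(0L, n, ploidy)
      L[fnd, ] <- matrix(seq_len(nlab), length(fnd), ploidy, byrow = TRUE)
      for (i in seq_len(n)) {
        if (is.na(mom[i])) next
        g1 <- if (alpha > 0 && stats::runif(1) < alpha)
          rep(L[mom[i], sample.int(ploidy, 1L)], 2L)
        else L[mom[i], sample.int(ploidy, half)]
        g2 <- if (alpha > 0 && stats::runif(1) < alpha)
          rep(L[dad[i], sample.int(ploidy, 1L)], 2L)
        else L[dad[i], sample.int(ploidy, half)]
        L[i, ] <- c(g1, g2)
      }
      U <- matrix(0L, n, nlab)
      for (k in seq_len(ploidy))
        U[cbind(seq_len(n), L[, k])] <- U[cbind(seq_len(n), L[, k])] + 1L
      acc <- acc + tcrossprod(U)
    }
  })
  acc * (1 / (n_reps * ploidy))
}

#' Compare a genomic relationship matrix with a pedigree oracle
#'
#' Classifies every pair of individuals from the pedigree (self,
#' parent-offspring, full-sib, half-sib, unrelated-founder pairs,
#' other) and reports, per class, the mean entry of `G`, of the oracle
#' matrix, and the mean absolute discrepancy.
#'
#' @param G Realised relationship matrix (dimnames = ids).
#' @param oracle Expected relationship matrix, e.g. from
#'   [gene_drop_relationship()].
#' @param ped Pedigree table covering the same ids.
#' @return Data.frame with one row per relationship class.
#' @export
validate_grm_against_pedigree <- function(G, oracle, ped) {
  ids <- ped$id
  if (!all(ids %in% rownames(G)) || !all(ids %in% rownames(oracle)))
    stop2("G or oracle lacks pedigree ids")
  G <- G[ids, ids]; oracle <- oracle[ids, ids]
  n <- length(ids)
  mom <- match(ped$mother, ids); dad <- match(ped$father, ids)
  cls <- matrix("other", n, n)
  founder <- is.na(mom)
  cls[outer(founder, founder, `&`)] <- "unrelated"
  po <- matrix(FALSE, n, n)
  for (i in which(!founder)) {
    po[i, c(mom[i], dad[i])] <- TRUE
    po[c(mom[i], dad[i]), i] <- TRUE
  }
  cls[po] <- "parent-offspring"
  off <- which(!founder)
  if (length(off) > 1) {
    sm <- outer(mom[off], mom[off], `==`)
    sd_ <- outer(dad[off], dad[off], `==`)
    cls[off, off][sm & sd_] <- "full-sib"
    cls[off, off][xor(sm, sd_)] <- "half-sib"
    cls[off, off][!sm & !sd_] <- "other"
  }
  diag(cls) <- "self"
  ut <- upper.tri(cls, diag = TRUE)
  df <- data.frame(class = cls[ut], g = G[ut], a = oracle[ut],
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, df$class), function(d)
    data.frame(class = d$class[1], n_pairs = nrow(d),
               mean_G = mean(d$g), mean_oracle = mean(d$a),
               mean_abs_diff = mean(abs(d$g - d$a)),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg
}
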