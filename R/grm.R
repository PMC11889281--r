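#' Allele frequencies from a dosage matrix
#'
#' `p_j = mean(dosage_j) / ploidy`, estimated by default over every
#' genotyped individual (parents and progeny), matching the convention
#' of building a single relationship matrix for the whole population.
#'
#' @param x A complete (imputed) [dosage_matrix()].
#' @param ids Optional subset of individuals (e.g. founders only) over
#'   which to estimate.
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
allele_frequencies <- function(x, ids = NULL) {
  stopifnot(inherits(x, "dosage_matrix"))
  if (!is.null(ids)) x <- x[ids, , drop = FALSE]
  if (anyNA(x)) stop2("dosage matrix contains missing entries; impute first")
  colMeans(unclass(x)) / ploidy(x)
}

#' Realised genomic relationship matrix for ploidy m
#'
#' VanRaden-type construction generalised to autopolyploid dosages:
#' with dosage matrix `M` (individuals x markers), frequencies `p_j` and
#' ploidy `m`, the centred matrix is `Z = M - m * 1 p'` and
#' `G = Z Z' / (m * sum_j p_j (1 - p_j))`. The denominator is the summed
#' polysomic Hardy-Weinberg dosage variance, so a non-inbred HWE panel
#' has mean diagonal 1; at `m = 2` the construction is exactly the
#' classical diploid VanRaden matrix. A small ridge
#' `epsilon * mean(diag(G))` is recorded and added to the diagonal by
#' downstream solvers to keep the matrix numerically positive definite.
#'
#' @param x A complete [dosage_matrix()].
#' @param freqs Allele frequencies; default [allele_frequencies()] of
#'   `x`. Markers with `p_j` of 0 or 1 (monomorphic) are rejected -
#'   filter first.
#' @param epsilon Relative ridge (default `1e-6`).
#' @return A `grm_result`: list with `G`, `freqs`, `denominator`,
#'   `epsilon` (absolute ridge), `ploidy`.
#' @export
build_grm <- function(x, freqs = allele_frequencies(x), epsilon = 1e-6) {
  stopifnot(inherits(x, "dosage_matrix"))
  m <- ploidy(x)
  if (length(freqs) != ncol(x))
    stop2("frequency vector length ", length(freqs),
          " does not match marker count ", ncol(x))
  if (any(freqs <= 0 | freqs >= 1))
    stop2("monomorphic marker(s) (p of 0 or 1) in frequency vector: ",
          paste(utils::head(colnames(x)[freqs <= 0 | freqs >= 1], 3),
                collapse = ", "))
  denom <- m * sum(freqs * (1 - freqs))
  if (denom <= 0) stop2("zero scaling denominator")
  Z <- sweep(unclass(x), 2L, m * freqs)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  structure(list(G = G, freqs = freqs, denominator = denom,
                 epsilon = epsilon * mean(diag(G)), ploidy = m),
            class = "grm_result")
}

#' @export
print.grm_result <- function(x, ...) {
  cat("grm_result:", nrow(x$G), "individuals,", length(x$freqs),
      "markers; mean diagonal", sprintf("%.4f", mean(diag(x$G))),
      "; denominator", sprintf("%.2f", x$denominator), "\n")
  invisible(x)
}

#' Read / write a relationship matrix as square CSV
#'
#' @param grm A `grm_result` or plain symmetric matrix.
#' @param path File path.
#' @return `write_grm()` returns `path` invisibly; `read_grm()` the
#'   matrix.
#' @export
write_grm <- function(grm, path) {
  G <- if (inherits(grm, "grm_result")) grm$G else grm
  df <- data.frame(id = rownames(G), G, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(id = "character"))
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$id
  if (nrow(G) != ncol(G) || !identical(rownames(G), colnames(G)))
    stop2("'", path, "' is not a square id-labelled matrix")
  G
}
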