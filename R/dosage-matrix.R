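#' Dosage matrix container
#'
#' A dosage matrix stores allele-dosage calls for `n` individuals at `p`
#' biallelic markers as an individuals-by-markers numeric matrix with a
#' ploidy attribute. In a tetraploid, dosages code the number of
#' alternate-allele copies: 0 (AAAA), 1 (AAAB), 2 (AABB), 3 (ABBB),
#' 4 (BBBB). Raw calls are integers in `0..ploidy` (or `NA`); after
#' mean-imputation entries may be fractional, which downstream
#' relationship-matrix arithmetic accepts.
#'
#' @param x Numeric matrix, individuals in rows (rownames = individual
#'   ids), markers in columns (colnames = marker ids).
#' @param ploidy Even integer >= 2 (default 4).
#' @param integral If `TRUE`, require integer-valued entries.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(x, ploidy = 4L, integral = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop2("dosage data must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop2("dosage matrix needs at least one individual and one marker")
  ploidy <- as.integer(ploidy)
  if (ploidy < 2L || ploidy %% 2L != 0L)
    stop2("ploidy must be an even integer >= 2, got ", ploidy)
  if (is.null(rownames(x))) rownames(x) <- paste0("ind", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop2("duplicate individual ids: ",
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop2("duplicate marker ids: ",
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.na(x) & (x < 0 | x > ploidy))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(x)) + 1
    j <- ((bad[1] - 1) %/% nrow(x)) + 1
    stop2("dosage out of range [0, ", ploidy, "]: value ", x[bad[1]],
          " at individual '", rownames(x)[i], "', marker '", colnames(x)[j], "'")
  }
  if (integral) {
    nonint <- which(!is.na(x) & abs(x - round(x)) > 1e-8)
    if (length(nonint)) {
      i <- ((nonint[1] - 1) %% nrow(x)) + 1
      j <- ((nonint[1] - 1) %/% nrow(x)) + 1
      stop2("non-integer dosage ", x[nonint[1]], " at individual '",
            rownames(x)[i], "', marker '", colnames(x)[j], "'")
    }
  }
  structure(x, ploidy = ploidy, class = c("dosage_matrix", "matrix", "array"))
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x), "individuals x", ncol(x), "markers, ploidy",
      attr(x, "ploidy"), "\n")
  nmiss <- sum(is.na(x))
  if (nmiss) cat("  missing entries:", nmiss,
                 sprintf("(%.2f%%)", 100 * nmiss / length(x)), "\n")
  invisible(x)
}

#' Ploidy of a dosage matrix
#' @param x A `dosage_matrix`.
#' @return Integer ploidy.
#' @export
ploidy <- function(x) {
  p <- attr(x, "ploidy")
  if (is.null(p)) stop2("object carries no ploidy attribute")
  p
}

# Subsetting keeps class/ploidy when the result is still a matrix.
#' @export
`[.dosage_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, ploidy = attr(x, "ploidy"),
                     class = c("dosage_matrix", "matrix", "array"))
  out
}

#' Read / write a dosage matrix as CSV
#'
#' The on-disk format is a plain CSV with an `id` column of individual
#' ids followed by one column per marker; missing calls are the literal
#' token `NA`. `write_dosage()` then `read_dosage()` round-trips the
#' matrix, ids and ploidy exactly.
#'
#' @param path File path.
#' @param ploidy Ploidy of the stored calls.
#' @return `read_dosage()` returns a `dosage_matrix`; `write_dosage()`
#'   returns `path` invisibly.
#' @export
read_dosage <- function(path, ploidy = 4L) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "id")
    stop2("dosage file '", path, "' must have an 'id' column followed by marker columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop2("non-numeric dosage entries in '", path, "'")
  rownames(m) <- as.character(df$id)
  dosage_matrix(m, ploidy = ploidy, integral = TRUE)
}

#' @rdname read_dosage
#' @param x A `dosage_matrix`.
#' @export
write_dosage <- function(x, path) {
  stopifnot(inherits(x, "dosage_matrix"))
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Filter markers by missingness, frequency and polymorphism
#'
#' Removes markers whose missing-call rate exceeds `max_missing`, whose
#' minor-allele frequency (computed from observed calls as
#' `min(p, 1 - p)` with `p = mean(dosage)/ploidy`) falls below `min_maf`,
#' and all monomorphic markers (zero variance among observed calls),
#' which would contribute nothing to — and, at the boundary, break — the
#' relationship-matrix denominator.
#'
#' @param x A `dosage_matrix`.
#' @param max_missing Maximum tolerated missing rate per marker, in \[0,1\].
#' @param min_maf Minimum minor-allele frequency, in \[0,1\].
#' @return A list with elements `matrix` (the filtered `dosage_matrix`)
#'   and `report` (data.frame of removed markers with a `reason` column).
#' @export
filter_markers <- function(x, max_missing = 0.2, min_maf = 0.01) {
  stopifnot(inherits(x, "dosage_matrix"))
  if (max_missing < 0 || max_missing > 1 || min_maf < 0 || min_maf > 1)
    stop2("thresholds must lie in [0, 1]")
  m <- ploidy(x)
  miss <- colMeans(is.na(x))
  p <- colMeans(x, na.rm = TRUE) / m
  vr <- apply(x, 2L, stats::var, na.rm = TRUE)
  mono <- is.na(vr) | vr == 0
  maf <- pmin(p, 1 - p)
  reason <- character(ncol(x))
  reason[maf < min_maf] <- "low_maf"
  reason[mono] <- "monomorphic"
  reason[miss > max_missing] <- "high_missing"
  drop <- reason != ""
  if (all(drop)) stop2("all ", ncol(x), " markers removed by filtering")
  report <- data.frame(marker = colnames(x)[drop],
                       missing_rate = unname(miss[drop]),
                       maf = unname(maf[drop]),
                       reason = reason[drop], stringsAsFactors = FALSE)
  list(matrix = x[, !drop, drop = FALSE], report = report)
}

#' Impute missing dosages by the marker mean
#'
#' Each missing call is replaced by the mean of the observed calls at
#' that marker; imputed values are generally fractional. Markers with no
#' observed calls cannot be imputed and raise an error.
#'
#' @param x A `dosage_matrix`.
#' @return A complete `dosage_matrix` (possibly fractional entries).
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "dosage_matrix"))
  if (!anyNA(x)) return(x)
  allmiss <- colSums(!is.na(x)) == 0
  if (any(allmiss))
    stop2("marker(s) with no observed calls cannot be imputed: ",
          paste(colnames(x)[allmiss], collapse = ", "))
  mu <- colMeans(x, na.rm = TRUE)
  out <- unclass(x)
  idx <- which(is.na(out), arr.ind = TRUE)
  out[idx] <- mu[idx[, 2]]
  dosage_matrix(out, ploidy = ploidy(x))
}
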