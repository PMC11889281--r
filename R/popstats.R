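#' Principal component analysis of the dosage matrix
#'
#' Column-centred, unscaled PCA of the individuals-by-markers dosage
#' matrix via [stats::prcomp()] (singular value decomposition), the
#' conventional treatment for population-structure screening of dosage
#' genotypes. Percent variance explained is the normalised squared
#' singular values; scores are reproducible up to sign.
#'
#' @param x A complete [dosage_matrix()].
#' @param n_components Components to retain (default
#'   `min(n - 1, markers)`).
#' @param scale. Scale markers to unit variance before decomposition
#'   (default `FALSE`).
#' @return A `pca_result`: `scores` (individuals x components),
#'   `percent_var`, `loadings`, `sdev`.
#' @export
pca_dosage <- function(x, n_components = NULL, scale. = FALSE) {
  stopifnot(inherits(x, "dosage_matrix"))
  if (anyNA(x)) stop2("dosage matrix contains missing entries; impute first")
  M <- unclass(x)
  full <- min(nrow(M) - 1L, ncol(M))
  if (full < 1L) stop2("matrix has rank 0; PCA undefined")
  if (is.null(n_components)) n_components <- full
  if (n_components > full)
    stop2("n_components must be <= min(n - 1, markers) = ", full)
  if (max(apply(M, 2L, stats::var)) == 0)
    stop2("constant dosage matrix; PCA undefined")
  pc <- stats::prcomp(M, center = TRUE, scale. = scale., rank. = n_components)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x,
                 percent_var = pct[seq_len(n_components)],
                 loadings = pc$rotation, sdev = pc$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "individuals,", ncol(x$scores),
      "components;", "PC1-3 %var:",
      paste(sprintf("%.1f", utils::head(x$percent_var, 3)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pearson (moment) coefficient of skewness with classification
#'
#' `g1 = m3 / m2^(3/2)` with population moments
#' `m_k = mean((x - mean(x))^k)` (no small-sample bias correction, the
#' convention of the classical moment estimator). Classification by the
#' conventional thresholds: |g1| < 0.5 approximately normal, 0.5-1.0
#' moderately skewed, > 1.0 highly skewed, with the direction (left /
#' right) given by the sign.
#'
#' @param x Numeric vector, `n >= 3`, non-constant.
#' @return List with `g1` and `class`.
#' @export
pearson_skewness <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop2("need n >= 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop2("zero variance; skewness undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  a <- abs(g1)
  cls <- if (a < 0.5) "approximately-normal"
  else paste0(if (a <= 1) "moderately-skewed(" else "highly-skewed(",
              if (g1 > 0) "right)" else "left)")
  list(g1 = g1, class = cls)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on the absolute deviations from the group centre,
#' delegated to [car::leveneTest()]. The default centre is the group
#' median (the robust Brown-Forsythe variant, suited to moderately
#' skewed, unbalanced samples); `center = mean` gives the classical
#' form.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (coerced to factor), >= 2 groups with
#'   >= 2 observations each.
#' @param center `stats::median` (default) or `mean`.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
levene_test <- function(values, groups, center = stats::median) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop2("need >= 2 groups")
  if (any(table(droplevels(groups)) < 2L))
    stop2("every group needs >= 2 observations")
  lt <- car::leveneTest(values, droplevels(groups), center = center)
  list(F = lt$`F value`[1], df1 = lt$Df[1], df2 = lt$Df[2],
       p_value = lt$`Pr(>F)`[1])
}

#' Per-trait descriptive summaries by cross type
#'
#' Builds the descriptive table of the phenotyped population: for each
#' trait, design subset (total population and, when the pedigree flags
#' one, the balanced factorial block) and cross type, the number of
#' phenotyped females, mean, median and skewness of their per-female
#' multi-year mean observations, together with Levene's test of
#' variance homogeneity between cross types within the subset. Groups
#' without records are reported as `N = 0` rows; Levene columns are
#' `NA` when fewer than two cross types have data.
#'
#' @param records Long-format phenotype records.
#' @param ped Pedigree table.
#' @param center Centring function for [levene_test()].
#' @return Data.frame with columns trait, subset, cross_type, N, mean,
#'   median, skewness, skew_class, levene_F, levene_p.
#' @export
describe_traits <- function(records, ped, center = stats::median) {
  subsets <- list(total = ped$id[!is.na(ped$mother)])
  bal <- balanced_subset_ids(ped)
  if (length(bal)) subsets$balanced_7x3 <- bal
  cts <- c("AAxAA", "AAxME")
  out <- list()
  for (tr in unique(records$trait)) {
    rec <- records[records$trait == tr, , drop = FALSE]
    imean <- tapply(rec$value, rec$id, mean)
    ict <- ped$cross_type[match(names(imean), ped$id)]
    for (ss in names(subsets)) {
      inset <- names(imean) %in% subsets[[ss]]
      vals <- split(imean[inset], factor(ict[inset], levels = cts))
      lev <- if (sum(vapply(vals, length, 0L) >= 2L) == 2L)
        levene_test(unlist(vals), rep(cts, vapply(vals, length, 0L)),
                    center = center)
      else list(F = NA_real_, p_value = NA_real_)
      for (ct in cts) {
        v <- vals[[ct]]
        sk <- if (length(v) >= 3L && stats::sd(v) > 0) pearson_skewness(v)
        else list(g1 = NA_real_, class = NA_character_)
        out[[length(out) + 1L]] <- data.frame(
          trait = tr, subset = ss, cross_type = ct, N = length(v),
          mean = if (length(v)) mean(v) else NA_real_,
          median = if (length(v)) stats::median(v) else NA_real_,
          skewness = sk$g1, skew_class = sk$class,
          levene_F = lev$F, levene_p = lev$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
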