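#' Correlation test for predictive ability
#'
#' Pearson correlation between predicted breeding values and mean
#' observations, with the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` and a two-sided p-value on
#' `n - 2` degrees of freedom (delegated to [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors, `n >= 3`, both non-constant.
#' @return List with `r`, `t`, `df`, `p_value`, `n`.
#' @export
correlation_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop2("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop2("correlation undefined: constant margin")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value, n = length(x))
}

# Per-fold LOO machinery at fixed variance components. Removing the
# masked female's records from V is done by low-rank downdating of the
# precomputed W = V^{-1}: with index set s removed,
#   (V_rr)^{-1} = W_rr - W_rs (W_ss)^{-1} W_sr,
# so for full vectors u, v with a_u = W u, B = W_ss,
#   u_r' (V_rr)^{-1} v_r = t1(u, v) - c_u' B^{-1} c_v,
#   t1 = u'a_v - u_s'a_v[s] - a_u[s]'v_s + u_s' B v_s,
#   c_u = a_u[s] - B u_s.
# Each fold then costs O(n * p) instead of a fresh n^3 solve.
loo_gebv <- function(y, X, zid, phen, Gt, sigma_a2, sigma_e2,
                     fold_ids = phen) {
  n <- length(y); p <- ncol(X)
  V <- sigma_a2 * tcrossprod(t(chol(Gt))[zid, , drop = FALSE])
  diag(V) <- diag(V) + sigma_e2
  Vc <- chol(V)
  Vinv <- chol2inv(Vc)
  aX <- Vinv %*% X
  ay <- drop(Vinv %*% y)
  # K columns for the validation individuals: k^{(i)} = sigma_a2 * Gt[id(r), i]
  Kcols <- sigma_a2 * Gt[zid, match(fold_ids, phen), drop = FALSE]
  aK <- Vinv %*% Kcols
  out <- numeric(length(fold_ids)); names(out) <- fold_ids
  for (f in seq_along(fold_ids)) {
    s <- which(phen[zid] == fold_ids[f])
    if (!length(s)) { out[f] <- NA_real_; next }
    B <- Vinv[s, s, drop = FALSE]
    Binv <- solve(B)
    u_all <- cbind(X, y, Kcols[, f])           # n x (p + 2)
    a_all <- cbind(aX, ay, aK[, f])
    # pairwise reduced-quadratic forms among {X cols, y, k}
    t1 <- crossprod(u_all, a_all)
    us <- u_all[s, , drop = FALSE]
    as_ <- a_all[s, , drop = FALSE]
    t1 <- t1 - crossprod(us, as_) - crossprod(as_, us) +
      crossprod(us, B %*% us)
    cu <- as_ - B %*% us
    Q <- t1 - crossprod(cu, Binv %*% cu)
    iX <- seq_len(p); iy <- p + 1L; ik <- p + 2L
    XtVX <- Q[iX, iX, drop = FALSE]
    b <- solve(XtVX, Q[iX, iy])
    out[f] <- Q[ik, iy] - sum(Q[ik, iX] * b)   # k' Vrr^{-1} (y - X b)
  }
  out
}

#' Leave-one-out cross-validated predictive ability
#'
#' Each phenotyped female is masked in turn: all her records are removed
#' from the training data, her GEBV is re-solved at variance components
#' fixed to the full-data REML estimates (or re-estimated per fold when
#' the model spec requests it), and paired with her unadjusted mean
#' observation across years. Predictive ability is the Pearson
#' correlation between the two, reported overall and within cross types
#' with the t-transform significance test.
#'
#' @param records,spec,grm,ped As in [fit_gblup()].
#' @param fit Optional pre-computed full-data `gblup_fit` (avoids
#'   re-fitting).
#' @return A `cv_result`: `folds` (id, cross_type, gebv, mean_obs),
#'   `overall` and `by_cross_type` correlation summaries, and `vc`.
#' @export
loo_predictive_ability <- function(records, spec, grm, ped, fit = NULL) {
  G <- if (inherits(grm, "grm_result")) grm$G else grm
  if (is.null(fit))
    fit <- fit_gblup(records, spec, grm, ped, compute_pev = FALSE)
  mf <- fit$model_frame
  if (length(mf$phen) < 3L)
    stop2("leave-one-out needs >= 3 phenotyped individuals, got ",
          length(mf$phen))
  eps <- fit$epsilon
  Gt <- G[mf$phen, mf$phen]
  diag(Gt) <- diag(Gt) + eps
  if (fit$spec$refit_vc) {
    gebv <- vapply(mf$phen, function(id) {
      keep <- mf$rec$id != id
      f <- fit_gblup(mf$rec[keep, , drop = FALSE], spec, grm, ped,
                     compute_pev = FALSE)
      unname(f$gebv[id])
    }, 0)
  } else {
    gebv <- loo_gebv(mf$y, mf$X, mf$zid, mf$phen, Gt,
                     fit$vc$sigma_a2, fit$vc$sigma_e2)
  }
  mean_obs <- tapply(mf$y, mf$phen[mf$zid], mean)[mf$phen]
  folds <- data.frame(id = mf$phen,
                      cross_type = ped$cross_type[match(mf$phen, ped$id)],
                      gebv = unname(gebv[mf$phen]),
                      mean_obs = unname(mean_obs),
                      stringsAsFactors = FALSE)
  summarise <- function(d) {
    if (nrow(d) < 3L || stats::sd(d$gebv) == 0 || stats::sd(d$mean_obs) == 0)
      return(list(n = nrow(d), r = NA_real_, t = NA_real_, p_value = NA_real_,
                  reason = "constant margin or n < 3"))
    c(correlation_test(d$gebv, d$mean_obs), list(reason = NA_character_))
  }
  by_ct <- lapply(split(folds, folds$cross_type), summarise)
  structure(list(trait = spec$trait, folds = folds,
                 overall = summarise(folds), by_cross_type = by_ct,
                 vc = fit$vc), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result for '", x$trait, "': overall r = ",
      sprintf("%.3f", x$overall$r), " (n = ", x$overall$n, ", p = ",
      format.pval(x$overall$p_value, digits = 3), ")\n", sep = "")
  for (ct in names(x$by_cross_type)) {
    s <- x$by_cross_type[[ct]]
    cat(sprintf("  %s: r = %s (n = %d)\n", ct,
                ifelse(is.na(s$r), "NA", sprintf("%.3f", s$r)), s$n))
  }
  invisible(x)
}

#' Sub-population cross-validation schemes
#'
#' Restricts the training phenotypes to a named sub-population and
#' re-runs the leave-one-out analysis inside it:
#' * `"total"` - all phenotyped females (identical to
#'   [loo_predictive_ability()]);
#' * `"AAxAA"` / `"AAxME"` - only females of that cross type;
#' * `"AAxAA*"` - `n_repeats` random draws of AAxAA females,
#'   size-matched to the AAxME female count, each analysed by LOO; the
#'   mean and spread of `r` over draws are returned (the training-set
#'   size effect).
#'
#' Variance components are re-estimated once per restricted training
#' set and then fixed across its folds. The relationship matrix and its
#' allele frequencies stay those of the full population.
#'
#' @param records,spec,grm,ped As in [fit_gblup()].
#' @param scheme One of `"total"`, `"AAxAA"`, `"AAxME"`, `"AAxAA*"`.
#' @param n_repeats Draws for the randomised scheme (default 1000, the
#'   conventional choice; reduce for desk-scale work).
#' @param seed RNG seed for the randomised scheme.
#' @return For deterministic schemes a `cv_result`; for `"AAxAA*"` a
#'   list with `mean_r`, `sd_r`, `r_values`, `n_per_draw`, `n_repeats`.
#' @export
subpopulation_cv <- function(records, spec, grm, ped, scheme = "total",
                             n_repeats = 1000L, seed = 1L) {
  stopifnot(scheme %in% c("total", "AAxAA", "AAxME", "AAxAA*"))
  rec <- records[records$trait == spec$trait, , drop = FALSE]
  ct_of <- function(ids) ped$cross_type[match(ids, ped$id)]
  if (scheme == "total")
    return(loo_predictive_ability(records, spec, grm, ped))
  if (scheme %in% c("AAxAA", "AAxME")) {
    keep <- rec[ct_of(rec$id) == scheme, , drop = FALSE]
    if (length(unique(keep$id)) < 3L)
      stop2("restriction '", scheme, "' leaves fewer than 3 phenotyped ",
            "individuals")
    return(loo_predictive_ability(keep, spec, grm, ped))
  }
  # AAxAA*: size-matched random subsets of the intra-specific females
  ids_aa <- unique(rec$id[ct_of(rec$id) == "AAxAA"])
  n_me <- length(unique(rec$id[ct_of(rec$id) == "AAxME"]))
  if (n_me < 3L) stop2("AAxME sub-population too small to size-match (",
                       n_me, " females)")
  if (length(ids_aa) < n_me) stop2("AAxAA smaller than AAxME; cannot subsample")
  rs <- with_seed(seed, vapply(seq_len(n_repeats), function(k) {
    sub <- sample(ids_aa, n_me)
    res <- tryCatch(
      loo_predictive_ability(rec[rec$id %in% sub, , drop = FALSE],
                             spec, grm, ped),
      error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$overall$r
  }, 0))
  list(scheme = "AAxAA*", mean_r = mean(rs, na.rm = TRUE),
       sd_r = stats::sd(rs, na.rm = TRUE), r_values = rs,
       n_per_draw = n_me, n_repeats = n_repeats)
}

#' Parent accuracy under different training restrictions
#'
#' Recomputes the Henderson accuracy of named (typically unphenotyped)
#' parents when the training phenotypes are restricted to different
#' sub-populations - the relationship-to-training-set experiment. Each
#' scheme names a set of phenotyped females whose records form the
#' training data; variance components are re-estimated per scheme. A
#' scheme with no records yields accuracy 0 for every parent (the
#' no-information limit, PEV = sigma_a^2 G_ii).
#'
#' @param records,spec,grm,ped As in [fit_gblup()].
#' @param parents Character vector of parent ids (must be in `G`).
#' @param schemes Named list; each element is either a character vector
#'   of training female ids or one of the shortcuts `"total"`,
#'   `"AAxAA"`, `"AAxME"`, `"balanced_subset"`, or `"progeny:<id>"`
#'   (females with father `<id>`).
#' @return Data.frame (parent x scheme) with accuracy, n_train and the
#'   scheme's variance components.
#' @export
parent_accuracy_profile <- function(records, spec, grm, ped, parents,
                                    schemes = list(total = "total")) {
  G <- if (inherits(grm, "grm_result")) grm$G else grm
  missing_par <- setdiff(parents, rownames(G))
  if (length(missing_par))
    stop2("parent(s) absent from G: ", paste(missing_par, collapse = ", "))
  rec <- records[records$trait == spec$trait, , drop = FALSE]
  resolve <- function(s) {
    if (is.character(s) && length(s) == 1L) {
      if (s == "total") return(unique(rec$id))
      if (s %in% c("AAxAA", "AAxME"))
        return(intersect(unique(rec$id),
                         ped$id[!is.na(ped$mother) & ped$cross_type == s]))
      if (s == "balanced_subset")
        return(intersect(unique(rec$id), balanced_subset_ids(ped)))
      if (startsWith(s, "progeny:"))
        return(intersect(unique(rec$id),
                         ped$id[!is.na(ped$father) &
                                  ped$father == sub("^progeny:", "", s)]))
    }
    intersect(unique(rec$id), s)
  }
  rows <- list()
  for (nm in names(schemes)) {
    train <- resolve(schemes[[nm]])
    sub <- rec[rec$id %in% train, , drop = FALSE]
    if (nrow(sub) == 0L) {
      rows[[nm]] <- data.frame(scheme = nm, parent = parents, accuracy = 0,
                               n_train = 0L, sigma_a2 = NA_real_,
                               sigma_e2 = NA_real_, stringsAsFactors = FALSE)
      next
    }
    fit <- fit_gblup(sub, spec, grm, ped, compute_pev = TRUE)
    rows[[nm]] <- data.frame(scheme = nm, parent = parents,
                             accuracy = unname(fit$accuracy[parents]),
                             n_train = length(unique(sub$id)),
                             sigma_a2 = fit$vc$sigma_a2,
                             sigma_e2 = fit$vc$sigma_e2,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$scheme, out$parent), ]
}
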