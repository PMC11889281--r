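#' Model specification for the GBLUP linear mixed model
#'
#' The model is `y = mu + Xb + Za + e` with `a ~ N(0, G sigma_a^2)` and
#' `e ~ N(0, I sigma_e^2)`. The intercept is always present; optional
#' fixed effects are `year`, `cross_type` and their interaction (the
#' interaction requires both main effects).
#'
#' @param trait Trait name to model.
#' @param fixed Character subset of
#'   `c("year", "cross_type", "year:cross_type")`.
#' @param refit_vc Cross-validation policy: re-estimate variance
#'   components inside each fold (`TRUE`) or fix them at the full-data
#'   estimates (`FALSE`, default).
#' @return A `model_spec` object.
#' @export
model_spec <- function(trait, fixed = "year", refit_vc = FALSE) {
  allowed <- c("year", "cross_type", "year:cross_type")
  bad <- setdiff(fixed, allowed)
  if (length(bad)) stop2("unknown fixed term(s): ", paste(bad, collapse = ", "))
  if ("year:cross_type" %in% fixed &&
      !all(c("year", "cross_type") %in% fixed))
    stop2("the year:cross_type interaction requires both main effects")
  structure(list(trait = trait, fixed = unique(fixed), refit_vc = refit_vc),
            class = "model_spec")
}

# Assemble record-level data for one trait: response y, fixed-effect
# design X (aliased columns dropped, term membership tracked), the
# record-to-individual index into the G ids, and bookkeeping.
build_model_frame <- function(records, spec, G_ids, ped) {
  rec <- records[records$trait == spec$trait, , drop = FALSE]
  if (!nrow(rec)) stop2("no records for trait '", spec$trait, "'")
  missG <- setdiff(unique(rec$id), G_ids)
  if (length(missG))
    stop2("phenotyped id(s) absent from G: ",
          paste(utils::head(missG, 5), collapse = ", "))
  phen <- sort(unique(rec$id))
  if (length(phen) < 2L) stop2("need >= 2 phenotyped individuals")
  zid <- match(rec$id, phen)
  ct <- ped$cross_type[match(rec$id, ped$id)]
  fr <- data.frame(year = factor(rec$year),
                   cross_type = factor(ct), stringsAsFactors = FALSE)
  terms <- c("(Intercept)", intersect(c("year", "cross_type",
                                        "year:cross_type"), spec$fixed))
  Xfull <- list(`(Intercept)` = matrix(1, nrow(rec), 1,
                                       dimnames = list(NULL, "(Intercept)")))
  # single-level factors yield an empty (fully aliased) block, not an error
  blk <- function(form) {
    if (any(vapply(all.vars(form), function(v) nlevels(fr[[v]]) < 2L, TRUE)))
      return(matrix(0, nrow(rec), 0))
    stats::model.matrix(form, fr)
  }
  if ("year" %in% terms) {
    mm <- blk(~year)
    Xfull$year <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  }
  if ("cross_type" %in% terms) {
    mm <- blk(~cross_type)
    Xfull$cross_type <- mm[, setdiff(colnames(mm), "(Intercept)"),
                           drop = FALSE]
  }
  if ("year:cross_type" %in% terms) {
    mm <- blk(~ year * cross_type)
    Xfull$`year:cross_type` <- mm[, grepl(":", colnames(mm)), drop = FALSE]
  }
  # sequential aliasing scan: keep only columns that increase rank
  X <- NULL; assign <- integer(0); df <- integer(length(terms))
  aliased <- character(0)
  names(df) <- terms
  for (k in seq_along(terms)) {
    blk <- Xfull[[terms[k]]]
    for (j in seq_len(ncol(blk))) {
      cand <- cbind(X, blk[, j])
      if (qr(cand)$rank > ifelse(is.null(X), 0L, qr(X)$rank)) {
        X <- cand
        colnames(X)[ncol(X)] <- colnames(blk)[j]
        assign <- c(assign, k)
        df[k] <- df[k] + 1L
      } else aliased <- c(aliased, colnames(blk)[j])
    }
  }
  if (qr(X)$rank < ncol(X)) stop2("fixed-effect design is rank deficient")
  list(y = rec$value, X = X, assign = assign, term_df = df, terms = terms,
       aliased = aliased, phen = phen, zid = zid, rec = rec)
}

# Profile the restricted likelihood over delta = sigma_e^2 / sigma_a^2
# via the spectral decomposition of the projected record-level kernel
# S K S, K = Z G Z'. Returns the REML-optimal variance components.
reml_profile <- function(y, X, C, lambda_range = c(1e-5, 1e5),
                         n_grid = 41L) {
  n <- length(y); p <- ncol(X)
  qx <- qr(X)
  SC <- C - qr.fitted(qx, C)
  Sy <- y - qr.fitted(qx, y)
  ev <- eigen(crossprod(SC), symmetric = TRUE)
  tol <- max(ev$values, 0) * 1e-10
  r <- sum(ev$values > tol)
  if (r == 0L) stop2("genomic kernel has rank 0 after projection")
  theta <- ev$values[seq_len(r)]
  U <- SC %*% ev$vectors[, seq_len(r), drop = FALSE]
  U <- sweep(U, 2L, sqrt(theta), "/")
  eta2 <- drop(crossprod(U, y))^2
  R0 <- max(sum(Sy^2) - sum(eta2), 0)
  n0 <- (n - p) - r
  if (n0 < 0L) { n0 <- 0L }                    # kernel spans the residual space
  nm <- n - p
  prof <- function(ldelta) {
    d <- 10^ldelta
    ss <- sum(eta2 / (theta + d)) + if (n0 > 0L) R0 / d else 0
    ld <- sum(log(theta + d)) + n0 * log(d)
    0.5 * (nm * log(nm / (2 * pi)) - nm - nm * log(ss) - ld)
  }
  lo <- log10(lambda_range[1]); hi <- log10(lambda_range[2])
  grid <- seq(lo, hi, length.out = n_grid)
  vals <- vapply(grid, prof, 0)
  k <- which.max(vals)
  bl <- grid[max(1L, k - 1L)]; bh <- grid[min(n_grid, k + 1L)]
  opt <- stats::optimize(prof, c(bl, bh), maximum = TRUE, tol = 1e-10)
  ldelta <- opt$maximum
  boundary <- ldelta <= lo + 1e-3 || ldelta >= hi - 1e-3
  delta <- 10^ldelta
  ss <- sum(eta2 / (theta + delta)) + if (n0 > 0L) R0 / delta else 0
  sigma_a2 <- ss / nm
  list(sigma_a2 = sigma_a2, sigma_e2 = delta * sigma_a2, delta = delta,
       boundary = boundary, profile_loglik = opt$objective)
}

# Dense restricted log-likelihood (Patterson-Thompson normalisation,
# including the + 0.5 log|X'X| term) and GLS/BLUP solves at given
# variance components. K = Z G Z' is passed pre-built.
gblup_solve <- function(y, X, K, sigma_a2, sigma_e2) {
  n <- length(y); p <- ncol(X)
  V <- sigma_a2 * K
  diag(V) <- diag(V) + sigma_e2
  R <- chol(V)
  VinvX <- backsolve(R, backsolve(R, X, transpose = TRUE))
  Vinvy <- backsolve(R, backsolve(R, y, transpose = TRUE))
  XtVinvX <- crossprod(X, VinvX)
  cov_b <- solve(XtVinvX)
  b <- drop(cov_b %*% crossprod(X, Vinvy))
  Py <- Vinvy - VinvX %*% (cov_b %*% crossprod(X, Vinvy))
  logdetV <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * ((n - p) * log(2 * pi) + logdetV +
                      determinant(XtVinvX, logarithm = TRUE)$modulus -
                      determinant(crossprod(X), logarithm = TRUE)$modulus +
                      sum(y * Py))
  list(R = R, VinvX = VinvX, Vinvy = Vinvy, cov_b = cov_b, b = b,
       Py = drop(Py), loglik = as.numeric(loglik))
}

#' Fit the GBLUP linear mixed model by REML
#'
#' Estimates the two variance components by restricted maximum
#' likelihood, profiling the restricted likelihood over the single
#' variance ratio `delta = sigma_e^2 / sigma_a^2` through the spectral
#' decomposition of the projected record-level kernel `Z G Z'` (a grid
#' on `log10(delta)` over \[1e-5, 1e5\] followed by Brent refinement),
#' then solves Henderson's mixed-model equations at the optimum.
#' Breeding values are predicted for every individual in `G`,
#' phenotyped or not (unphenotyped parents and males are carried by
#' their genomic relationships to the phenotyped females); prediction
#' error variances and Henderson accuracies
#' `sqrt(1 - PEV / (sigma_a^2 G_ii))` are returned per individual,
#' together with a sequential Wald chi-squared table for the fixed
#' effects.
#'
#' @param records Long-format phenotype records (id, trait, year,
#'   value).
#' @param spec A [model_spec()].
#' @param grm A [build_grm()] result (or bare PSD matrix with id
#'   dimnames).
#' @param ped Pedigree table supplying `cross_type` per individual.
#' @param vc Optional fixed variance components
#'   `list(sigma_a2=, sigma_e2=)`; skips REML (used by cross-validation
#'   under the fixed-VC policy).
#' @param compute_pev Compute per-individual PEV/accuracy (the dominant
#'   cost at large scale; switch off when only variance components and
#'   GEBVs are needed).
#' @param lambda_range,n_grid Profiling range and coarse-grid size for
#'   the variance ratio.
#' @return A `gblup_fit`: variance components (`vc`), `heritability`,
#'   fixed effects (`b`, `se_b`), `wald` table, `gebv`, `pev`,
#'   `accuracy`, `g_ii`, plus bookkeeping used by the cross-validation
#'   layer.
#' @export
fit_gblup <- function(records, spec, grm, ped, vc = NULL,
                      compute_pev = TRUE, lambda_range = c(1e-5, 1e5),
                      n_grid = 41L) {
  stopifnot(inherits(spec, "model_spec"))
  G <- if (inherits(grm, "grm_result")) grm$G else grm
  eps <- if (inherits(grm, "grm_result")) grm$epsilon else 1e-6 * mean(diag(G))
  mf <- build_model_frame(records, spec, rownames(G), ped)
  diag(G) <- diag(G) + eps                    # effective (ridged) G throughout
  Gt <- G[mf$phen, mf$phen]
  Lc <- tryCatch(chol(Gt), error = function(e)
    stop2("G is not positive definite on the phenotyped block even after ",
          "regularisation: ", conditionMessage(e)))
  C <- t(Lc)[mf$zid, , drop = FALSE]          # C C' = Z Gt Z'
  if (is.null(vc)) {
    vc <- reml_profile(mf$y, mf$X, C, lambda_range, n_grid)
    vc$convergence <- TRUE
  } else {
    stopifnot(is.numeric(vc$sigma_a2), is.numeric(vc$sigma_e2))
    vc$delta <- vc$sigma_e2 / vc$sigma_a2
    vc$boundary <- FALSE; vc$convergence <- TRUE
  }
  K <- tcrossprod(C)
  sol <- gblup_solve(mf$y, mf$X, K, vc$sigma_a2, vc$sigma_e2)
  vc$loglik <- sol$loglik
  # GEBV for every individual in G: a = sigma_a2 * G[, phen] Z' P y
  t_phen <- rowsum(sol$Py, mf$zid)[, 1]
  Gcross <- G[, mf$phen, drop = FALSE]
  gebv <- drop(vc$sigma_a2 * (Gcross %*% t_phen))
  names(gebv) <- rownames(G)
  g_ii <- diag(G)
  pev <- accuracy <- NULL
  if (compute_pev) {
    W <- t(Gcross)[mf$zid, , drop = FALSE]    # n x N, row r = G[id(r), ]
    VinvW <- backsolve(sol$R, backsolve(sol$R, W, transpose = TRUE))
    PW <- VinvW - sol$VinvX %*% (sol$cov_b %*% crossprod(mf$X, VinvW))
    quad <- colSums(W * PW)
    pev <- pmax(vc$sigma_a2 * g_ii - vc$sigma_a2^2 * quad, 0)
    names(pev) <- rownames(G)
    accuracy <- henderson_accuracy(pev, vc$sigma_a2, g_ii)
  }
  wald <- wald_table(mf, sol$R)
  nrec <- table(factor(mf$rec$id, levels = rownames(G)))
  structure(list(trait = spec$trait, spec = spec,
                 vc = vc[c("sigma_a2", "sigma_e2", "delta", "loglik",
                           "boundary", "convergence")],
                 heritability = vc$sigma_a2 / (vc$sigma_a2 + vc$sigma_e2),
                 b = stats::setNames(sol$b, colnames(mf$X)),
                 se_b = stats::setNames(sqrt(diag(sol$cov_b)), colnames(mf$X)),
                 cov_b = sol$cov_b,
                 wald = wald, gebv = gebv, pev = pev, accuracy = accuracy,
                 g_ii = g_ii,
                 n_records = stats::setNames(as.integer(nrec), names(nrec)),
                 aliased = mf$aliased, phen = mf$phen, model_frame = mf,
                 epsilon = eps),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("gblup_fit for trait '", x$trait, "': ", length(x$model_frame$y),
      " records on ", length(x$phen), " individuals\n", sep = "")
  cat(sprintf("  sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f, logREML = %.3f%s\n",
              x$vc$sigma_a2, x$vc$sigma_e2, x$heritability, x$vc$loglik,
              if (x$vc$boundary) " (boundary)" else ""))
  cat("  fixed effects:", paste(names(x$b), collapse = ", "), "\n")
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`, the additive fraction of
#' the phenotypic variance on an individual-record basis.
#'
#' @param vc List with `sigma_a2` and `sigma_e2` (e.g. `fit$vc`).
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(vc) {
  tot <- vc$sigma_a2 + vc$sigma_e2
  if (tot <= 0) stop2("total variance must be positive")
  vc$sigma_a2 / tot
}

#' Henderson accuracy of predicted breeding values
#'
#' `accuracy_i = sqrt(1 - PEV_i / (sigma_a^2 * G_ii))`, where `G_ii` is
#' the diagonal of the relationship matrix (`1 + F` for an individual
#' with inbreeding coefficient `F`). A negative radicand (possible
#' through numerical error when PEV is at its ceiling) is clamped to 0
#' with a warning.
#'
#' @param pev Prediction error variance(s), >= 0.
#' @param sigma_a2 Additive variance, > 0.
#' @param g_ii Relationship-matrix diagonal entries, > 0.
#' @return Accuracies in \[0, 1\].
#' @export
henderson_accuracy <- function(pev, sigma_a2, g_ii) {
  if (sigma_a2 <= 0) stop2("sigma_a2 must be positive")
  if (any(g_ii <= 0)) stop2("G_ii must be positive")
  if (any(pev < 0)) stop2("PEV must be non-negative")
  rad <- 1 - pev / (sigma_a2 * g_ii)
  if (any(rad < -1e-8))
    warning("negative accuracy radicand clamped to 0", call. = FALSE)
  sqrt(pmin(pmax(rad, 0), 1))
}

# Sequential (incremental) Wald chi-squared table: whiten by the
# Cholesky factor of V, then decompose the fitted sum of squares by
# term in fitting order. Terms whose columns were all aliased keep a
# row with df = 0.
wald_table <- function(mf, R) {
  Xw <- backsolve(R, mf$X, transpose = TRUE)
  yw <- backsolve(R, mf$y, transpose = TRUE)
  qx <- qr(Xw)
  comp <- qr.qty(qx, yw)[seq_len(ncol(Xw))]^2
  terms <- mf$terms[-1]                        # intercept not tested
  if (!length(terms))
    return(data.frame(term = character(0), df = integer(0),
                      chisq = numeric(0), p_value = numeric(0)))
  out <- data.frame(term = terms,
                    df = as.integer(mf$term_df[terms]),
                    chisq = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(terms)) {
    idx <- which(mf$assign == k + 1L)
    if (!length(idx)) next                     # fully aliased term
    out$chisq[k] <- sum(comp[idx])
    out$p_value[k] <- stats::pchisq(out$chisq[k], length(idx),
                                    lower.tail = FALSE)
  }
  out$aliased <- out$df == 0L
  out
}

#' Sequential Wald chi-squared tests for the fixed effects
#'
#' Returns the incremental Wald table of a fitted model: terms are
#' tested in fitting order (year, then cross type, then their
#' interaction), each chi-squared statistic measuring the improvement
#' from adding the term's estimable columns given all earlier terms,
#' with variance components held at their REML estimates. Terms whose
#' columns are all aliased are reported with df = 0 and flagged, not
#' dropped.
#'
#' @param fit A `gblup_fit`.
#' @return Data.frame with columns term, df, chisq, p_value, aliased.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  fit$wald
}
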