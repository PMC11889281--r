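# Independent oracles used across the suite. These deliberately use only
# dense base-R linear algebra (solve/determinant) and exhaustive
# enumeration - none of the package's eigendecomposition/profiling code
# paths - so they can arbitrate its results.

# Exhaustive gamete enumeration: list all choose(m, m/2) homolog subsets
# of a parent carrying d alternate alleles; mix in the double-reduction
# component (one homolog duplicated) with weight alpha.
enum_gamete_dist <- function(d, m = 4, alpha = 0) {
  half <- m / 2
  homologs <- c(rep(1, d), rep(0, m - d))
  subs <- utils::combn(m, half)
  counts <- apply(subs, 2, function(ix) sum(homologs[ix]))
  biv <- tabulate(counts + 1L, nbins = half + 1L) / ncol(subs)
  if (alpha == 0) return(biv)
  dr <- sapply(0:half, function(k) mean(2 * homologs == k))
  (1 - alpha) * biv + alpha * dr
}

# Dense REML + mixed-model-equation oracle. Profiles the restricted
# likelihood over delta = sigma_e2/sigma_a2 by direct V-inversion on a
# grid with Brent refinement, then solves Henderson's MME explicitly.
# Same likelihood normalisation as the package documents
# (Patterson-Thompson including the + 0.5 log|X'X| term).
mme_oracle <- function(y, X, Z, Gt, lrange = c(-5, 5)) {
  n <- length(y); p <- ncol(X)
  K <- Z %*% Gt %*% t(Z)
  restricted_ll <- function(sa2, se2) {
    V <- sa2 * K + se2 * diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                         determinant(V)$modulus +
                         determinant(XtViX)$modulus -
                         determinant(crossprod(X))$modulus +
                         sum(y * (P %*% y))))
  }
  prof <- function(ld) {
    d <- 10^ld
    V <- K + d * diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    sa2 <- sum(y * (P %*% y)) / (n - p)
    restricted_ll(sa2, d * sa2)
  }
  grid <- seq(lrange[1], lrange[2], length.out = 41)
  vals <- vapply(grid, prof, 0)
  k <- which.max(vals)
  opt <- stats::optimize(prof, c(grid[max(1, k - 1)], grid[min(41, k + 1)]),
                         maximum = TRUE, tol = 1e-10)
  d <- 10^opt$maximum
  V <- K + d * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  sa2 <- sum(y * (P %*% y)) / (n - p)
  se2 <- d * sa2
  Cmat <- rbind(cbind(crossprod(X), t(X) %*% Z),
                cbind(t(Z) %*% X, crossprod(Z) + d * solve(Gt)))
  sol <- solve(Cmat, rbind(t(X) %*% y, t(Z) %*% y))
  Cinv <- solve(Cmat)
  list(sigma_a2 = sa2, sigma_e2 = se2, delta = d,
       loglik = restricted_ll(sa2, se2),
       b = sol[seq_len(p), 1],
       gebv = sol[-seq_len(p), 1],
       pev = se2 * diag(Cinv)[-seq_len(p)])
}

# Random small GBLUP fixture: q individuals with a valid (binomial
# dosage derived) G, 1-2 records each over two years.
random_fixture <- function(q = 8, n_markers = 40, seed = 1) {
  set.seed(seed)
  ids <- sprintf("i%02d", 1:q)
  M <- matrix(rbinom(q * n_markers, 4, runif(n_markers, 0.2, 0.8)[
    rep(1:n_markers, each = q)]), q, n_markers,
    dimnames = list(ids, paste0("m", 1:n_markers)))
  dos <- dosage_matrix(M, ploidy = 4)
  fl <- filter_markers(dos, max_missing = 0, min_maf = 0.05)
  grm <- build_grm(fl$matrix)
  nrec <- sample(1:2, q, replace = TRUE)
  rec <- data.frame(
    id = rep(ids, nrec),
    trait = "t",
    year = unlist(lapply(nrec, function(k) c("Y1", "Y2")[seq_len(k)])),
    value = NA_real_, stringsAsFactors = FALSE)
  u <- drop(scale(M) %*% rnorm(n_markers)) / sqrt(n_markers)
  names(u) <- ids
  yeff <- c(Y1 = 0, Y2 = 0.5)
  rec$value <- 3 + yeff[rec$year] + u[rec$id] + rnorm(nrow(rec), 0, 0.7)
  ped <- data.frame(id = ids, mother = NA_character_, father = NA_character_,
                    sex = "F", species = "AA", cross_id = NA_character_,
                    cross_type = "founder", stringsAsFactors = FALSE)
  list(records = rec, grm = grm, ped = ped, ids = ids)
}

# Build dense y, X, Z, Gt (ridged, package convention) for a fitted
# model frame, for feeding the oracle.
dense_pieces <- function(fit, grm) {
  mf <- fit$model_frame
  G <- grm$G
  diag(G) <- diag(G) + grm$epsilon
  Gt <- G[mf$phen, mf$phen]
  Z <- matrix(0, length(mf$y), length(mf$phen))
  Z[cbind(seq_along(mf$y), mf$zid)] <- 1
  list(y = mf$y, X = mf$X, Z = Z, Gt = Gt, phen = mf$phen)
}

# Small study-like population for integration-style tests.
small_population <- function(seed = 11, n_markers = 400,
                             traits = NULL, years = c("Y1", "Y2"),
                             dropout = 0.05) {
  if (is.null(traits))
    traits <- list(trait_architecture("t", mean = 10, h2 = 0.6,
                                      range = c(0, 25),
                                      cross_type_effect = -1.5))
  cfg <- sim_config(
    n_markers = n_markers, seed = seed,
    designs = list(factorial_design("4x6", 4, 6, n_me_males = 1,
                                    balanced_females = 3,
                                    extra_crosses = 3)),
    offspring_min = 6, offspring_mean = 10, offspring_max = 16,
    traits = traits, years = years, dropout = dropout)
  simulate_population(cfg)
}
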