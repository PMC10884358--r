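## Independent oracles used across the test files.  These deliberately
## re-derive results by brute force (per-point evaluation, exhaustive
## enumeration, double loops) so they share no code path with the
## implementation they check.

## All permutations of a vector (small n only).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

## Naive spherical-spline interpolation: solve the bordered system once,
## then evaluate the series at each target electrode in a plain loop.
oracle_spline <- function(source, target, values, config = spline_config()) {
  ps <- source$positions / sqrt(rowSums(source$positions^2))
  pt <- target$positions / sqrt(rowSums(target$positions^2))
  ns <- nrow(ps)
  G <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      G[i, j] <- g_kernel(max(-1, min(1, sum(ps[i, ] * ps[j, ]))), config)
    }
  }
  A <- rbind(cbind(G + diag(config$ridge, ns), 1), c(rep(1, ns), 0))
  sol <- solve(A, c(values, 0))
  c_coef <- sol[seq_len(ns)]
  c0 <- sol[ns + 1L]
  out <- numeric(nrow(pt))
  for (t in seq_len(nrow(pt))) {
    acc <- c0
    for (i in seq_len(ns)) {
      acc <- acc + c_coef[i] *
        g_kernel(max(-1, min(1, sum(pt[t, ] * ps[i, ]))), config)
    }
    out[t] <- acc
  }
  out
}

## Exhaustive modified-k-means: enumerate every assignment of n items to K
## classes (all classes non-empty), compute the optimal class maps
## (dominant eigenvector of the weighted outer-product sum) and the
## weighted explained variance; return the maximum.
oracle_kmeans_best <- function(X, w, K) {
  n <- ncol(X)
  best <- -Inf
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  for (row in seq_len(nrow(grid))) {
    L <- grid[row, ]
    if (length(unique(L)) < K) next
    obj <- 0
    for (k in seq_len(K)) {
      sel <- L == k
      S <- X[, sel, drop = FALSE] %*% (w[sel] * t(X[, sel, drop = FALSE]))
      obj <- obj + max(eigen(S, symmetric = TRUE)$values)
    }
    obj <- obj / sum(w)
    if (obj > best) best <- obj
  }
  best
}

## Random canonical map on n channels.
rand_map <- function(n, seed = NULL) {
  gen <- function() canonicalize_map(stats::rnorm(n))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

## Tiny literal study used by several files.
toy_study <- function(id = "Toy 2024", seed = 42, n_maps = 2,
                      montage = montage_1020(), findings = NULL) {
  maps <- withr::with_seed(seed, {
    matrix(stats::rnorm(montage$n_channels * n_maps), ncol = n_maps)
  })
  colnames(maps) <- LETTERS[seq_len(n_maps)]
  ms_study(id, montage, maps, n_subjects = 10, findings = findings)
}
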