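test_that("spatial correlation and shared variance identities hold", {
  u <- rand_map(19, seed = 1)
  expect_equal(spatial_correlation(u, u), 1, tolerance = 1e-12)
  expect_equal(spatial_correlation(u, -u), -1, tolerance = 1e-12)
  expect_equal(shared_variance(u, u), 100, tolerance = 1e-9)
  expect_equal(shared_variance(u, -u), 100, tolerance = 1e-9)

  ## hand oracle: orthogonal pair, dot product 1 - 1 - 1 + 1 = 0
  a <- canonicalize_map(c(1, -1, 1, -1, 0, 0, 0, 0))
  b <- canonicalize_map(c(1, 1, -1, -1, 0, 0, 0, 0))
  expect_equal(spatial_correlation(a, b), 0, tolerance = 1e-12)
  expect_equal(shared_variance(a, b), 0, tolerance = 1e-12)

  ## invariance to scale, polarity and argument order
  v <- rand_map(19, seed = 2)
  expect_equal(shared_variance(3 * u, -0.2 * v), shared_variance(v, u),
               tolerance = 1e-12)
  expect_error(spatial_correlation(u, rnorm(32)), "mismatch")
})

test_that("global map dissimilarity matches its closed forms and oracle", {
  u <- rand_map(19, seed = 3)
  a <- canonicalize_map(c(1, -1, 1, -1, 0, 0, 0, 0))
  b <- canonicalize_map(c(1, 1, -1, -1, 0, 0, 0, 0))
  expect_equal(map_dissimilarity(u, u), 0, tolerance = 1e-12)
  expect_equal(map_dissimilarity(u, -u), 0, tolerance = 1e-12)
  expect_equal(map_dissimilarity(a, b), sqrt(2), tolerance = 1e-12)
  expect_equal(map_dissimilarity(u, -u, polarity = "signed"), 2,
               tolerance = 1e-12)

  ## brute-force: polarity-folded L2 distance between canonical maps
  for (s in 1:15) {
    x <- rand_map(19, seed = 100 + s)
    y <- rand_map(19, seed = 200 + s)
    d <- map_dissimilarity(x, y)
    expect_equal(d, min(sqrt(sum((x - y)^2)), sqrt(sum((x + y)^2))),
                 tolerance = 1e-12)
  }
})

test_that("similarity matrix satisfies its invariants on simple atlases", {
  m <- montage_1020()
  u <- rand_map(19, seed = 4)
  s1 <- ms_study("S1", m, cbind(A = u, B = -u), 10)
  sim <- similarity_matrix(ms_atlas(list(s1)))
  expect_equal(unname(sim$values), matrix(100, 2, 2), tolerance = 1e-9)

  ## three orthogonal maps -> zero off-diagonal
  q <- qr.Q(qr(cbind(rand_map(19, 1), rand_map(19, 2), rand_map(19, 3))))
  q <- apply(q, 2, function(col) canonicalize_map(col - mean(col)))
  ## re-orthogonalize inside the zero-mean subspace
  q[, 2] <- canonicalize_map(q[, 2] - sum(q[, 2] * q[, 1]) * q[, 1])
  q[, 3] <- canonicalize_map(q[, 3] - sum(q[, 3] * q[, 1]) * q[, 1] -
                               sum(q[, 3] * q[, 2]) * q[, 2])
  colnames(q) <- c("A", "B", "C")
  sim3 <- similarity_matrix(ms_atlas(list(ms_study("S1", m, q, 5))))
  off <- sim3$values[upper.tri(sim3$values)]
  expect_true(all(abs(off) < 1e-9))
  expect_equal(unname(diag(sim3$values)), rep(100, 3))
  expect_lt(max(abs(sim3$values - t(sim3$values))), 1e-9)
})

test_that("cross-montage similarity resamples to the smaller montage", {
  ## the same prototypes seen through 19- and 64-channel montages
  m19 <- montage_1020()
  m64 <- sim_montage(64, seed = 3)
  pr <- sim_prototypes(3, m64, seed = 0)
  s64 <- ms_study("Hi 64", m64, pr$maps, 10)
  s19 <- ms_study("Lo 19", m19, prototype_maps(pr, m19), 10)
  sim <- similarity_matrix(ms_atlas(list(s19, s64)))
  block <- sim$values[1:3, 4:6]   # cross-study block, matched classes
  expect_true(all(diag(block) >= 99))
  expect_true(all(sim$values >= 0 & sim$values <= 100))
  expect_lt(max(abs(sim$values - t(sim$values))), 1e-9)
})

test_that("classical MDS reproduces Euclidean-realizable configurations", {
  ## 3-4-5 right triangle is exactly 2-D embeddable
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 3
  D[1, 3] <- D[3, 1] <- 4
  D[2, 3] <- D[3, 2] <- 5
  emb <- mds_embed(D, dims = 2)
  expect_equal(as.matrix(dist(emb$coordinates)), unname(D),
               tolerance = 1e-9, ignore_attr = TRUE)

  ## 4 known 3-D points: construct distances, recover them
  P <- withr::with_seed(7, matrix(rnorm(12), 4, 3))
  D4 <- as.matrix(dist(P))
  emb4 <- mds_embed(D4, dims = 3)
  expect_equal(as.matrix(dist(emb4$coordinates)), unname(D4),
               tolerance = 1e-9, ignore_attr = TRUE)

  ## identical maps -> all-zero embedding (with a zero-padding warning)
  expect_warning(z <- mds_embed(matrix(0, 3, 3), dims = 2), "padding")
  expect_equal(unname(z$coordinates), matrix(0, 3, 2))
})

test_that("own Torgerson scaling agrees with stats::cmdscale", {
  at <- sim_atlas(n_studies = 4, seed = 9)
  D <- dissimilarity_matrix(similarity_matrix(at))
  emb <- mds_embed(D, dims = 3)
  ref <- stats::cmdscale(D, k = 3, eig = TRUE)
  ## same embedding up to per-axis sign
  expect_equal(abs(unname(emb$coordinates)), abs(unname(ref$points)),
               tolerance = 1e-8)
  expect_equal(emb$eigenvalues[1:3], ref$eig[1:3], tolerance = 1e-8)
  ## deterministic sign rule: largest-|coordinate| entry positive
  for (k in 1:3) {
    ax <- emb$coordinates[, k]
    expect_gte(ax[which.max(abs(ax))], 0)
  }
})

test_that("dissimilarities of one-montage atlases double-center cleanly", {
  ## polarity-unambiguous fixture: all maps perturbed around ONE prototype
  ## so every pairwise r > 0 and |r|-folding never distorts; then d is the
  ## plain chordal distance of unit vectors and -1/2 J d^2 J is near-PSD
  m <- montage_1020()
  pr <- sim_prototypes(1, m, seed = 3)
  maps <- withr::with_seed(5, {
    vapply(1:12, function(i) canonicalize_map(pr$maps[, 1] + 0.3 * rnorm(19)),
           numeric(19))
  })
  n <- ncol(maps)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- map_dissimilarity(maps[, i],
                                                             maps[, j])
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D^2 %*% J
  expect_gt(min(eigen((B + t(B)) / 2, symmetric = TRUE)$values), -1e-6)
})

test_that("MDS space preserves the prototype cloud structure", {
  skip_if_not_installed("cluster")
  at <- sim_atlas(seed = 2)   # 20 studies, 5 prototypes, noise sd 0.3 rad
  truth <- attr(at, "truth")
  emb <- mds_embed(dissimilarity_matrix(similarity_matrix(at)), dims = 3)
  sil <- cluster::silhouette(truth$class, dist(emb$coordinates))
  expect_gt(mean(sil[, 3]), 0.6)
})
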