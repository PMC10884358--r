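test_that("noiseless prototype copies are an exact fixed point", {
  a <- canonicalize_map(c(1, -1, 1, -1, 0, 0, 0, 0, 1, -1, 1, -1, 0, 0, 0, 0, 0, 0, 0))
  b <- canonicalize_map(c(1, 1, -1, -1, 0, 0, 0, 0, 1, 1, -1, -1, 0, 0, 0, 0, 0, 0, 0))
  X <- cbind(a, a, -a, b, b, -b)
  sol <- modified_kmeans(X, K = 2, restarts = 10, seed = 1)
  expect_equal(sol$objective, 1, tolerance = 1e-12)
  ## meta-maps equal the prototypes up to sign
  sv <- 100 * crossprod(cbind(a, b), sol$maps)^2
  expect_equal(unname(sort(apply(sv, 1, max))), c(100, 100),
               tolerance = 1e-9)
  expect_true(all(tabulate(sol$assignments, 2) > 0))
})

test_that("a single item with K = 1 returns the item itself", {
  v <- rand_map(19, seed = 5)
  sol <- modified_kmeans(cbind(v), K = 1, restarts = 1, seed = 1)
  expect_equal(sol$objective, 1, tolerance = 1e-12)
  expect_equal(abs(sum(sol$maps[, 1] * v)), 1, tolerance = 1e-12)
  expect_error(modified_kmeans(cbind(v), K = 2), "<=")
})

test_that("k-means attains the exhaustive-search optimum on tiny instances", {
  ## 8 items around 2 prototypes, enumerate all 2^8 assignments
  pr <- sim_prototypes(2, montage_1020(), seed = 3)
  X <- withr::with_seed(11, {
    vapply(rep(1:2, each = 4), function(k) {
      canonicalize_map(pr$maps[, k] + 0.4 * rnorm(19))
    }, numeric(19))
  })
  w <- withr::with_seed(12, sample(5:40, 8, replace = TRUE))
  sol <- modified_kmeans(X, w, K = 2, restarts = 20, seed = 2)
  best <- oracle_kmeans_best(X, w, K = 2)
  expect_equal(sol$objective, best, tolerance = 1e-9)
})

test_that("objective is polarity-invariant and weights act like replication", {
  pr <- sim_prototypes(3, montage_1020(), seed = 6)
  X <- withr::with_seed(21, {
    vapply(rep(1:3, each = 4), function(k) {
      canonicalize_map(pr$maps[, k] + 0.3 * rnorm(19))
    }, numeric(19))
  })
  w <- rep(c(7, 3, 12), each = 4)
  init <- c(1L, 5L, 9L)
  sol <- modified_kmeans(X, w, K = 3, restarts = 1, init = init)

  ## flipping item polarities changes nothing
  flip <- rep(c(1, -1), length.out = 12)
  solf <- modified_kmeans(sweep(X, 2, flip, "*"), w, K = 3, restarts = 1,
                          init = init)
  expect_equal(solf$objective, sol$objective, tolerance = 1e-12)
  expect_equal(unname(abs(colSums(solf$maps * sol$maps))), rep(1, 3),
               tolerance = 1e-9)

  ## doubling a weight equals duplicating the item
  X2 <- cbind(X, X[, 4])
  w2 <- w; w2[4] <- w[4] * 2
  wdup <- c(w, w[4])
  sol_w <- modified_kmeans(X, w2, K = 3, restarts = 1, init = init)
  sol_d <- modified_kmeans(X2, wdup, K = 3, restarts = 1, init = init)
  expect_equal(sol_w$objective, sol_d$objective, tolerance = 1e-12)
  expect_equal(unname(abs(colSums(sol_w$maps * sol_d$maps))), rep(1, 3),
               tolerance = 1e-9)
})

test_that("identical seeds reproduce solutions bit-identically", {
  at <- sim_atlas(n_studies = 6, seed = 3)
  r1 <- metacluster(at, k_min = 4, k_max = 5, restarts = 5, seed = 9)
  r2 <- metacluster(at, k_min = 4, k_max = 5, restarts = 5, seed = 9)
  expect_identical(lapply(r1$solutions, `[[`, "maps"),
                   lapply(r2$solutions, `[[`, "maps"))
  expect_identical(lapply(r1$solutions, `[[`, "assignments"),
                   lapply(r2$solutions, `[[`, "assignments"))
})

test_that("objective is non-decreasing in K and the elbow sits at the truth", {
  at <- sim_atlas(n_studies = 12, seed = 1)   # 5 generating prototypes
  run <- metacluster(at, k_min = 4, k_max = 7, restarts = 20, seed = 5)
  obj <- vapply(run$solutions, `[[`, 0, "objective")
  expect_true(all(diff(obj) >= -1e-9))
  gains <- diff(obj)   # gain attained by moving to K = 5, 6, 7
  expect_equal(which.max(gains), 1L, ignore_attr = TRUE)
})

test_that("duplicate items trigger the empty-cluster reseed and still fill K", {
  v1 <- rand_map(19, seed = 1)
  v2 <- rand_map(19, seed = 2)
  X <- cbind(v1, v1, v1, v2)
  sol <- modified_kmeans(X, K = 3, restarts = 10, seed = 4)
  expect_true(all(tabulate(sol$assignments, 3) > 0))
})

test_that("class alignment recovers correspondences across K", {
  pr <- sim_prototypes(5, montage_1020(), seed = 8)
  m <- montage_1020()
  sol4 <- as_metasolution(pr$maps[, 1:4], m)
  ## 5-class maps: a permutation of the 4 plus one new orthogonal class
  perm <- c(3L, 1L, 4L, 2L, 5L)
  sol5 <- as_metasolution(pr$maps[, perm], m)
  run <- structure(list(solutions = list(`4` = sol4, `5` = sol5),
                        items = NULL, weights = NULL, index = NULL,
                        montage = m, seed = NULL, alignment = NULL),
                   class = "ms_metaclusters")
  al <- align_solutions(run)
  ## aligned 5-solution: first 4 classes match solution 4's order, new last
  sv <- 100 * crossprod(sol4$maps, al$solutions[["5"]]$maps)^2
  expect_true(all(diag(sv[, 1:4]) > 99.999))
  expect_true(all(sv[, 5] < 25))

  ## matching equals exhaustive permutation search on the SV table
  svtab <- 100 * crossprod(sol4$maps, sol5$maps)^2
  best <- -Inf; best_p <- NULL
  for (p in all_perms(1:5)) {
    tot <- sum(svtab[cbind(1:4, p[1:4])])
    if (tot > best) { best <- tot; best_p <- p[1:4] }
  }
  got <- al$alignment$K5$matched
  expect_equal(sum(svtab[cbind(1:4, got)]), best, tolerance = 1e-9)

  ## reference ordering with the solution's own maps is the identity
  run2 <- align_solutions(run, reference = sol4$maps)
  expect_equal(run2$alignment$base$order, 1:4)

  ## manual override is applied and validated
  run3 <- align_solutions(run, override = list(`4` = c(2, 1, 3, 4)))
  expect_equal(run3$alignment$override_K4, c(2L, 1L, 3L, 4L))
  expect_error(align_solutions(run, override = list(`4` = c(1, 1, 2, 3))),
               "permutation")
})

test_that("prepared items compose study resampling with weighting", {
  at <- sim_atlas(n_studies = 2, channels = c(19, 64),
                  subjects_range = c(42, 42), seed = 6)
  prep <- prepare_items(at, montage_1020())
  expect_equal(ncol(prep$items), 10L)
  expect_equal(prep$weights, rep(42, 10))
  ## equals per-map resample_map output
  s2 <- at$studies[[2]]
  op <- spline_operator(s2$montage, montage_1020())
  expect_equal(unname(prep$items[, 6]),
               unname(resample_map(s2$maps[, 1], op)), tolerance = 1e-12)
})

test_that("meta-clustering runs serialize to JSON and back", {
  at <- sim_atlas(n_studies = 5, seed = 2)
  run <- metacluster(at, k_min = 4, k_max = 5, restarts = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_metaclusters(run, path)
  run2 <- read_metaclusters(path)
  expect_equal(run2$solutions[["4"]]$maps, run$solutions[["4"]]$maps,
               tolerance = 1e-12)
  expect_identical(run2$solutions[["5"]]$assignments,
                   run$solutions[["5"]]$assignments)
  expect_equal(run2$weights, run$weights)
})
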