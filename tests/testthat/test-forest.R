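test_that("fractional hyperparameters resolve by ceiling with a floor of one", {
  expect_identical(resolve_fraction(0.01, 55), 1L)
  expect_identical(resolve_fraction(1, 9), 9L)
  expect_identical(resolve_fraction(0.13, 50), 7L)
  expect_identical(resolve_fraction(0.25, 10), 3L)
  expect_error(resolve_fraction(0, 10), "fraction")
  expect_error(resolve_fraction(1.2, 10), "fraction")
})

test_that("the tuned profiles carry the documented settings", {
  nb <- forest_profile("non-bootstrap")
  expect_false(nb$bootstrap)
  expect_identical(nb$n_trees, 30L)
  expect_equal(nb$max_features, 0.25)
  expect_equal(nb$min_leaf, 0.01)
  bs <- forest_profile("bootstrap")
  expect_true(bs$bootstrap)
  expect_identical(bs$n_trees, 50L)
  expect_equal(bs$bootstrap_size, 1)
  expect_equal(bs$min_leaf, 0.13)
  expect_error(forest_config(min_leaf = 0), "min_leaf")
})

test_that("best_split finds the zero-SSR split on perfectly ordered data", {
  X <- cbind(c(1, 2, 3, 4), c(5, 5, 5, 5))
  y <- c(1, 1, 10, 10)
  sp <- best_split(X, y)
  expect_identical(sp$feature, 1L)
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$ssr, 0)
})

test_that("best_split returns NULL on pure or unsplittable nodes", {
  X <- cbind(c(1, 2, 3, 4))
  expect_null(best_split(X, y = rep(7, 4)))
  expect_null(best_split(cbind(rep(1, 4)), y = c(1, 2, 3, 4)))
  expect_null(best_split(X, y = c(1, 2, 3, 4), min_leaf = 3L))
})

test_that("best_split agrees with exhaustive enumeration on small instances", {
  set.seed(42)
  for (case in 1:200) {
    n <- sample(2:8, 1)
    f <- sample(1:4, 1)
    # coarse integer grids provoke duplicated values and exact SSR ties
    X <- matrix(sample(0:3, n * f, replace = TRUE), n, f)
    y <- sample(0:4, n, replace = TRUE)
    ml <- sample(1:2, 1)
    got <- best_split(X, y, min_leaf = ml)
    want <- oracle_best_split(X, y, min_leaf = ml)
    if (max(y) - min(y) == 0) want <- NULL  # pure-node contract
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$ssr, want$ssr, tolerance = 1e-9)
      expect_true(got$feature %in% want$features)
    }
  }
})

test_that("q_priority tie-break picks the feature ranked first for the target OTU", {
  # features 2 and 5 induce identical partitions -> exact SSR tie
  X <- matrix(0, 6, 6)
  X[, 2] <- c(1, 1, 2, 2, 3, 3)
  X[, 5] <- c(10, 10, 20, 20, 30, 30)
  y <- c(0, 0, 5, 5, 9, 9)
  prio <- list()
  prio[[1]] <- c(2L, 3L, 4L, 5L, 6L)
  sp <- best_split(X, y, features = c(2L, 5L), target_otu = 1L,
                   tiebreak = "q_priority", priorities = prio)
  expect_identical(sp$feature, 2L)
  prio[[1]] <- c(5L, 3L, 4L, 2L, 6L)
  sp <- best_split(X, y, features = c(2L, 5L), target_otu = 1L,
                   tiebreak = "q_priority", priorities = prio)
  expect_identical(sp$feature, 5L)
  expect_error(best_split(X, y, features = c(2L, 5L),
                          tiebreak = "q_priority"), "priority")
})

test_that("an unrestricted single tree without bootstrap reproduces its training targets", {
  set.seed(7)
  for (case in 1:5) {
    X <- matrix(stats::runif(12 * 5), 12, 5)  # distinct feature vectors
    y <- stats::runif(12)
    cfg <- forest_config(n_trees = 1, bootstrap = FALSE, max_features = 1,
                         max_depth = -1, min_leaf = 0.01)
    fo <- fit_forest(X, y, config = cfg)
    expect_equal(predict_forest(fo, X), y, tolerance = 1e-12)
  }
})

test_that("constant targets and single-leaf trees predict the training mean", {
  set.seed(8)
  X <- matrix(stats::runif(20), 10, 2)
  fo <- fit_forest(X, rep(3.5, 10), config = forest_config(n_trees = 5))
  expect_equal(predict_forest(fo, X), rep(3.5, 10))
  # min_leaf = 1 (whole dataset) forces root leaves
  y <- stats::runif(10)
  fo2 <- fit_forest(X, y, config = forest_config(n_trees = 3, min_leaf = 1))
  expect_equal(unname(predict_forest(fo2, X[1:2, ])), rep(mean(y), 2))
})

test_that("forest predictions stay within the observed target range", {
  set.seed(9)
  for (cfg in list(forest_profile("non-bootstrap"),
                   forest_profile("bootstrap"))) {
    X <- matrix(stats::runif(60), 12, 5)
    y <- stats::runif(12, 2, 5)
    fo <- fit_forest(X, y, config = cfg)
    pred <- predict_forest(fo, matrix(stats::runif(25, -1, 2), 5, 5))
    expect_true(all(pred >= min(y) - 1e-12 & pred <= max(y) + 1e-12))
  }
})

test_that("identical data, config and seed give bit-identical forests", {
  X <- matrix(stats::runif(40), 8, 5)
  y <- stats::runif(8)
  cfg <- forest_profile("bootstrap")
  set.seed(123); f1 <- fit_forest(X, y, config = cfg)
  set.seed(123); f2 <- fit_forest(X, y, config = cfg)
  expect_identical(f1, f2)
  q <- matrix(stats::runif(15), 3, 5)
  expect_identical(predict_forest(f1, q), predict_forest(f2, q))
})

test_that("predict_forest rejects feature-dimension mismatches", {
  fo <- fit_forest(matrix(1:8, 4, 2), c(1, 2, 3, 4),
                   config = forest_config(n_trees = 1))
  expect_error(predict_forest(fo, matrix(1:9, 3, 3)), "features")
})

test_that("priority_table ranks partners by ascending Q with index ties", {
  Q <- matrix(10, 4, 4)
  Q[1, ] <- c(NA, 3, 1, 2)
  expect_identical(priority_table(Q)[[1]], c(3L, 4L, 2L))
  # all-equal row: index order, owner excluded
  expect_identical(priority_table(Q)[[3]][1:2], c(1L, 2L))
  # first element is the row argmin
  set.seed(5)
  Qr <- matrix(stats::runif(36), 6, 6)
  Qr <- (Qr + t(Qr)) / 2
  pt <- priority_table(Qr)
  for (i in 1:6) {
    others <- setdiff(1:6, i)
    expect_identical(pt[[i]][1], others[which.min(Qr[i, others])])
  }
})
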