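make_complete <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, 0.1, 2), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
  m
}

test_that("read/write round-trips values, mask and labels in both dialects", {
  m <- make_complete(6)
  mask <- inject_missing(m, 0.2, seed = 4)
  for (fmt in c("phylip_square", "csv")) {
    f <- withr::local_tempfile()
    write_distance_matrix(m, mask, f, format = fmt)
    back <- read_distance_matrix(f, format = fmt)
    expect_identical(back$mask, mask)
    expect_identical(rownames(back$values), rownames(m))
    expect_equal(back$values[!mask], m[!mask], tolerance = 1e-12)
    expect_true(all(is.na(back$values[mask])))
  }
})

test_that("phylip writer emits the expected skeleton and sentinel", {
  m <- make_complete(4)
  mask <- matrix(FALSE, 4, 4)
  mask[1, 2] <- mask[2, 1] <- TRUE
  f <- withr::local_tempfile()
  write_distance_matrix(m, mask, f, format = "phylip_square")
  lines <- readLines(f)
  expect_identical(lines[1], "4")
  expect_length(strsplit(lines[2], " ")[[1]], 5)
  expect_identical(strsplit(lines[2], " ")[[1]][3], "NA")
})

test_that("single sentinel cell is flagged without disturbing the rest", {
  f <- withr::local_tempfile()
  writeLines(c("2", "A 0 0.5", "B ? 0"), f)
  got <- read_distance_matrix(f)
  expect_true(got$mask[2, 1])
  expect_identical(sum(got$mask), 1L)
  expect_equal(got$values[1, 2], 0.5)
})

test_that("parse errors name the offending cell", {
  bad <- list(
    nonsquare = c("3", "A 0 1 2", "B 1 0 3"),
    duplabels = c("2", "A 0 1", "A 1 0"),
    diag_missing = c("2", "A NA 1", "B 1 0"),
    negative = c("2", "A 0 -3", "B -3 0")
  )
  msgs <- c("rows", "duplicate", "diagonal", "negative")
  for (i in seq_along(bad)) {
    f <- withr::local_tempfile()
    writeLines(bad[[i]], f)
    expect_error(read_distance_matrix(f), msgs[i])
  }
})

test_that("inject_missing masks the floor-count of pairs, symmetrically", {
  m <- make_complete(9)
  mask <- inject_missing(m, 0.05, seed = 1)
  expect_identical(sum(mask), 2L)  # floor(0.05 * 36) = 1 pair
  expect_identical(mask, t(mask))
  expect_false(any(diag(mask)))
  m12 <- make_complete(12)
  for (f in c(0.1, 0.3, 0.6)) {
    mk <- inject_missing(m12, f, seed = 2)
    expect_identical(sum(mk), as.integer(2 * floor(f * 66)))
    # every column keeps an observed off-diagonal entry
    expect_true(all(colSums(!mk) - 1 >= 1))
  }
})

test_that("inject_missing is reproducible under seed and rejects infeasible fractions", {
  m <- make_complete(8)
  expect_identical(inject_missing(m, 0.4, seed = 9),
                   inject_missing(m, 0.4, seed = 9))
  expect_error(inject_missing(make_complete(4), 1), "reduce the missing")
  expect_error(inject_missing(m, 0), "fraction")
})

test_that("zero-pair fractions give an all-false mask", {
  m <- make_complete(5)
  expect_false(any(inject_missing(m, 0.05, seed = 1)))  # floor(.5) = 0
})

test_that("initial_guess is identity on complete symmetric matrices", {
  m <- make_complete(6)
  expect_equal(initial_guess(m, matrix(FALSE, 6, 6)), m)
})

test_that("initial_guess imputes column means then symmetrises", {
  # column-0/1 trace: observed col entries 4 and 6, so the masked pair gets
  # 6 and 4 before symmetrisation and 5 after
  v <- matrix(c(0, NA, 4,
                NA, 0, 6,
                4, 6, 0), 3, byrow = TRUE)
  mask <- matrix(FALSE, 3, 3)
  mask[1, 2] <- mask[2, 1] <- TRUE
  out <- initial_guess(v, mask)
  expect_equal(out[1, 2], 5)
  expect_equal(out[2, 1], 5)
  expect_equal(out[!mask], v[!mask])
})

test_that("initial_guess output is symmetric with zero diagonal on random masks", {
  for (s in 1:5) {
    m <- make_complete(8, seed = s)
    mask <- inject_missing(m, 0.3, seed = s)
    v <- m; v[mask] <- NA
    out <- initial_guess(v, mask)
    expect_identical(out, t(out))
    expect_identical(diag(out), setNames(rep(0, 8), rownames(m)))
    expect_false(anyNA(out))
  }
})

test_that("initial_guess errors on a fully missing column", {
  m <- make_complete(4)
  mask <- matrix(FALSE, 4, 4)
  mask[-1, 1] <- mask[1, -1] <- TRUE
  v <- m; v[mask] <- NA
  expect_error(initial_guess(v, mask), "no observed")
})

test_that("column_order sorts by missing count, skipping complete columns", {
  mask <- matrix(FALSE, 3, 3)
  mask[c(2, 3), 1] <- TRUE   # counts 2, 0, 1
  mask[2, 3] <- TRUE
  expect_identical(column_order(mask)$order, c(3L, 1L))
  expect_identical(column_order(mask)$missing_counts, c(2L, 0L, 1L))
  # all tied and nonzero: index order
  tie <- matrix(FALSE, 4, 4)
  tie[1, 2] <- tie[2, 1] <- tie[3, 4] <- tie[4, 3] <- TRUE
  expect_identical(column_order(tie)$order, 1:4)
  expect_identical(column_order(matrix(FALSE, 5, 5))$order, integer(0))
})

test_that("set_difference_error is zero-iff-equal, scale-invariant, guarded", {
  a <- matrix(c(0, 2, 2, 0), 2)
  b <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(set_difference_error(a, a), 0)
  expect_equal(set_difference_error(a, b), 0.25)
  expect_equal(set_difference_error(3 * a, 3 * b), 0.25)
  expect_gt(set_difference_error(a, b), 0)
  expect_error(set_difference_error(matrix(0, 2, 2), b), "zero")
  expect_error(set_difference_error(a, matrix(0, 3, 3)), "dimensions")
})
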