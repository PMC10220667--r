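test_that("spectral initialization reproduces fully observed low-rank data", {
  set.seed(11)
  # full-rank case: truncation at min(C, Tk) is the full SVD
  M <- matrix(rnorm(30), 5, 6)
  fac <- svd_initialize(masked_matrix(M), rank = 5)
  expect_lt(max(abs(fitted(fac) - M)), 1e-10)
  # rank-1 outer product at r = 1
  a <- rnorm(7); b <- rnorm(9)
  fac1 <- svd_initialize(masked_matrix(outer(a, b)), rank = 1)
  expect_lt(max(abs(fitted(fac1) - outer(a, b))), 1e-10)
  # singular values nonincreasing, factors orthonormal
  expect_true(all(diff(diag(fac$core)) <= 1e-12))
  expect_lt(max(abs(crossprod(fac$left) - diag(5))), 1e-8)
  expect_lt(max(abs(crossprod(fac$right) - diag(5))), 1e-8)
  expect_error(svd_initialize(masked_matrix(M), rank = 6), "invalid rank")
})

test_that("spectral initialization of a subsampled matrix tracks the truth", {
  # 20 x 24 rank-2 with 25% hidden: enough observations per line that the
  # rescaled truncated SVD already correlates strongly with the truth
  set.seed(21)
  hits <- 0
  for (k in 1:5) {
    truth <- random_lowrank(20, 24, 2)
    mask <- uniform_mask(20, 24, 0.25)
    fac <- svd_initialize(masked_matrix(truth, mask), rank = 2)
    if (cor(fitted(fac)[!mask], truth[!mask]) > 0.9) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("solve_core matches brute-force least squares", {
  set.seed(31)
  for (r in c(1, 2, 3)) {
    X <- random_orthonormal(7, r)
    Y <- random_orthonormal(9, r)
    blk <- masked_matrix(matrix(rnorm(63), 7, 9), uniform_mask(7, 9, 0.3))
    expect_lt(max(abs(solve_core(X, Y, blk) - brute_force_core(X, Y, blk))),
              1e-8)
  }
  # exact factor model is recovered exactly under a full mask
  X <- random_orthonormal(6, 2); Y <- random_orthonormal(8, 2)
  S0 <- matrix(rnorm(4), 2, 2)
  blk <- masked_matrix(X %*% S0 %*% t(Y))
  expect_lt(max(abs(solve_core(X, Y, blk) - S0)), 1e-10)
  # all-zero observations give a zero core
  zblk <- masked_matrix(matrix(0, 6, 8), uniform_mask(6, 8, 0.2))
  expect_lt(max(abs(solve_core(X, Y, zblk))), 1e-12)
  # rank-deficient system: 4 observed entries cannot pin down 9 unknowns
  tiny <- masked_matrix(matrix(rnorm(16), 4, 4),
                        matrix(c(rep(TRUE, 4), rep(FALSE, 12)), 4, 4))
  expect_error(solve_core(random_orthonormal(4, 3),
                          random_orthonormal(4, 3), tiny),
               "singular core system")
})

test_that("cost follows the masked Frobenius definition", {
  set.seed(41)
  X <- random_orthonormal(5, 2); Y <- random_orthonormal(6, 2)
  S0 <- matrix(rnorm(4), 2, 2)
  exact <- masked_matrix(X %*% S0 %*% t(Y), uniform_mask(5, 6, 0.2))
  expect_lt(completion_cost(X, Y, exact), 1e-10)
  # direct recomputation from the definition on a random instance
  blk <- masked_matrix(matrix(rnorm(30), 5, 6), uniform_mask(5, 6, 0.3))
  S <- solve_core(X, Y, blk)
  resid <- (blk$values - X %*% S %*% t(Y))[blk$mask]
  expect_equal(completion_cost(X, Y, blk), sqrt(sum(resid^2)),
               tolerance = 1e-12)
})

test_that("complete_block recovers hidden entries of incoherent data", {
  set.seed(51)
  truth <- random_lowrank(30, 28, 3)
  mask <- uniform_mask(30, 28, 0.15)
  res <- complete_block(masked_matrix(truth, mask), rank = 3)
  hid <- !mask
  expect_gt(cor(res$completed[hid], truth[hid]), 0.999)
  relerr <- sqrt(sum((res$completed[hid] - truth[hid])^2) /
                   sum(truth[hid]^2))
  expect_lt(relerr, 1e-3)
  # the returned pieces are mutually consistent
  expect_equal(res$completed, fitted(res$factorization))
  expect_equal(res$final_cost,
               completion_cost(res$factorization$left,
                               res$factorization$right,
                               masked_matrix(truth, mask)),
               tolerance = 1e-8)
})

test_that("complete_block on a fully observed block reproduces it", {
  set.seed(61)
  truth <- random_lowrank(12, 10, 3)
  res <- complete_block(masked_matrix(truth), rank = 3)
  expect_lt(max(abs(res$completed - truth)), 1e-8)
})

test_that("non-completable and non-finite blocks raise informative errors", {
  mask <- matrix(TRUE, 4, 5); mask[3, ] <- FALSE
  blk <- masked_matrix(matrix(rnorm(20), 4, 5), mask)
  err <- tryCatch(complete_block(blk, rank = 2), error = identity)
  expect_s3_class(err, "optrepair_infeasible")
  expect_equal(err$rows, 3L)
  vals <- matrix(rnorm(20), 4, 5); vals[2, 2] <- NaN
  expect_error(complete_block(masked_matrix(vals), rank = 2),
               "non-finite")
})

test_that("cost trace is nonincreasing and factors stay orthonormal", {
  set.seed(71)
  for (k in 1:5) {
    truth <- random_lowrank(15, 18, 3) +
      matrix(rnorm(15 * 18, sd = 0.2), 15, 18)
    res <- complete_block(masked_matrix(truth, uniform_mask(15, 18, 0.2)),
                          rank = 3)
    expect_false(is.unsorted(rev(res$cost_trace)))
    f <- res$factorization
    expect_lt(max(abs(crossprod(f$left) - diag(f$rank))), 1e-8)
    expect_lt(max(abs(crossprod(f$right) - diag(f$rank))), 1e-8)
  }
})
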