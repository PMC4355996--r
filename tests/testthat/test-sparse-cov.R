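test_that("sample correlation matches the textbook formula and its contracts", {
  # hand-computable 4 x 2 case: r = S_xy / sqrt(S_xx S_yy) with centered sums
  x <- cbind(a = c(1, 2, 4, 7), b = c(2, 1, 5, 9))
  xc <- sweep(x, 2, colMeans(x))
  r_hand <- sum(xc[, 1] * xc[, 2]) / sqrt(sum(xc[, 1]^2) * sum(xc[, 2]^2))
  r <- sample_correlation(x)
  expect_equal(r[1, 2], r_hand, tolerance = 1e-12)
  expect_equal(diag(r), c(a = 1, b = 1))

  # identical columns are perfectly correlated
  x2 <- cbind(c(1, 3, 2, 5), c(1, 3, 2, 5))
  expect_equal(sample_correlation(x2)[1, 2], 1.0)

  # a single feature gives the 1 x 1 identity
  expect_equal(unname(sample_correlation(matrix(c(1, 2, 4), 3, 1))),
               matrix(1, 1, 1))

  # constant features are refused by index
  expect_error(sample_correlation(cbind(c(1, 2, 3), c(5, 5, 5))), "2")
  expect_error(sample_correlation(matrix(1:4, 2, 2)[1, , drop = FALSE]),
               "2 samples")
})

test_that("the objective evaluates its three terms correctly", {
  # R = R_hat = I: every term vanishes
  expect_equal(penalized_cor_objective(diag(4), diag(4), lam = 3, tau = 0.2), 0)
  # 1-d scalar arithmetic: 0.5 (2-1)^2 - 0.1 log 2
  expect_equal(penalized_cor_objective(matrix(2), matrix(1), lam = 5, tau = 0.1),
               0.5 - 0.1 * log(2), tolerance = 1e-12)
  # L1 term counts both symmetric off-diagonal entries
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(penalized_cor_objective(r, diag(2), lam = 1, tau = 0),
               0.25 + 1.0, tolerance = 1e-12)
  # log-determinant undefined off the PD cone
  expect_error(penalized_cor_objective(matrix(c(1, 2, 2, 1), 2), diag(2), 0, 0.1),
               "positive definite")
})

test_that("solver input contracts are enforced", {
  expect_error(solve_penalized_correlation(matrix(c(1, 0.5, 0.1, 1), 2), 0.1),
               "symmetric")
  expect_error(solve_penalized_correlation(diag(2), lam = -0.1), "lam")
  expect_error(solve_penalized_correlation(diag(2), lam = 0.1, tau = 0), "tau")
})

test_that("at lam = 0 the minimizer is the eigenvalue closed form", {
  tau <- 1e-4
  # identity input: diagonal value (1 + sqrt(1 + 4 tau)) / 2
  f <- solve_penalized_correlation(diag(3), lam = 0, tau = tau)
  expect_equal(diag(f$r_tilde), rep((1 + sqrt(1 + 4 * tau)) / 2, 3),
               tolerance = 1e-12)
  expect_true(all(f$r_tilde[upper.tri(f$r_tilde)] == 0))

  # random symmetric inputs up to d = 20
  for (d in c(2, 5, 11, 20)) {
    r_hat <- random_correlation(d, seed = d)
    f <- solve_penalized_correlation(r_hat, lam = 0, tau = tau)
    eg <- eigen(r_hat, symmetric = TRUE)
    expected <- eg$vectors %*%
      (((eg$values + sqrt(eg$values^2 + 4 * tau)) / 2) * t(eg$vectors))
    expect_equal(f$r_tilde, expected, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # degenerate 1 x 1 block
  f1 <- solve_penalized_correlation(matrix(0.5), lam = 0.3, tau = tau)
  expect_equal(f1$r_tilde[1, 1], (0.5 + sqrt(0.25 + 4 * tau)) / 2,
               tolerance = 1e-12)
})

test_that("identity targets keep zero off-diagonals at any lam", {
  for (lam in c(0, 0.1, 1, 10)) {
    f <- solve_penalized_correlation(diag(4), lam = lam, tau = 1e-4)
    expect_true(all(f$r_tilde[upper.tri(f$r_tilde)] == 0))
    expect_true(f$converged)
  }
})

test_that("the 2x2 solution matches a dense grid-search oracle", {
  tau <- 1e-4
  r_hat <- matrix(c(1, 0.6, 0.6, 1), 2)
  for (lam in c(0.1, 0.3, 0.7)) {
    f <- solve_penalized_correlation(r_hat, lam = lam, tau = tau)
    oracle <- grid_search_2x2(r_hat, lam, tau)
    expect_lte(f$objective, oracle$objective + 1e-6)
    expect_equal(f$r_tilde[1, 1], oracle$diag, tolerance = 1e-4)
    expect_equal(f$r_tilde[1, 2], oracle$off, tolerance = 1e-4)
  }
  # lam = 0.7 soft-thresholds the 0.6 correlation to exactly zero
  f <- solve_penalized_correlation(r_hat, lam = 0.7, tau = tau)
  expect_identical(f$r_tilde[1, 2], 0)
})

test_that("the solution is SPD, symmetric, and stationary", {
  for (seed in 1:4) {
    r_hat <- random_correlation(10, n = 14, seed = seed)
    f <- solve_penalized_correlation(r_hat, lam = 0.15)
    expect_lt(max(abs(f$r_tilde - t(f$r_tilde))), 1e-10)
    expect_gt(min(eigen(f$r_tilde, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_lt(f$stationarity, 1e-4)
    expect_equal(f$objective,
                 objective_oracle(f$r_tilde, f$r_hat, 0.15, 1e-4),
                 tolerance = 1e-10)
  }
})

test_that("sparsity is monotone in lam and saturates at the diagonal limit", {
  lams <- c(0.02, 0.1, 0.25, 0.5, 1, 5)
  for (seed in 1:3) {
    r_hat <- random_correlation(10, n = 15, seed = 100 + seed)
    zeros <- vapply(lams, function(l) {
      f <- solve_penalized_correlation(r_hat, lam = l)
      sum(f$r_tilde[upper.tri(f$r_tilde)] == 0)
    }, 0)
    expect_true(all(diff(zeros) >= 0))
    # lam well beyond max |off-diagonal| kills everything; diagonals follow
    # the scalar closed form
    f <- solve_penalized_correlation(r_hat, lam = 5)
    expect_equal(sum(f$r_tilde[upper.tri(f$r_tilde)] != 0), 0)
    rii <- diag(r_hat)
    expect_equal(diag(f$r_tilde), (rii + sqrt(rii^2 + 4e-4)) / 2,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("warm starts do not change the solution", {
  r_hat <- random_correlation(8, seed = 9)
  cold <- solve_penalized_correlation(r_hat, lam = 0.2)
  warm <- solve_penalized_correlation(r_hat, lam = 0.2,
                                      init = solve_penalized_correlation(r_hat, lam = 0.3)$r_tilde)
  expect_equal(cold$r_tilde, warm$r_tilde, tolerance = 1e-5)
})

test_that("rescaling to covariance preserves scale and sparsity", {
  # identity correlation with variances (4, 9) gives diag(4, 9)
  ce <- correlation_to_covariance(diag(2), c(4, 9))
  expect_equal(ce$sigma, diag(c(4, 9)))
  # off-diagonal 0.5 with variances (1, 4): 0.5 * 1 * 2 = 1
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(correlation_to_covariance(r, c(1, 4))$sigma[1, 2], 1.0)
  # exact zeros survive the rescaling
  r3 <- diag(3); r3[1, 2] <- r3[2, 1] <- 0.4
  s3 <- correlation_to_covariance(r3, c(2, 3, 5))$sigma
  expect_identical(s3[1, 3], 0); expect_identical(s3[2, 3], 0)
  # contracts
  expect_error(correlation_to_covariance(diag(2), c(1, 0)), "positive")
  expect_error(correlation_to_covariance(diag(2), c(1, 2, 3)), "length")
})
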