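# Independent oracles used across the test files. These deliberately avoid
# the package's own computational paths.

# dense multivariate normal log-density via base determinant() and solve()
dense_mvn_logdensity <- function(x, mu, sigma) {
  p <- length(mu)
  ld <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus)
  md <- stats::mahalanobis(x, mu, sigma)
  -0.5 * (p * log(2 * pi) + ld + md)
}

# the penalized correlation objective recomputed from its definition
objective_oracle <- function(r, r_hat, lam, tau) {
  sum((r - r_hat)^2) / 2 - tau * log(det(r)) +
    lam * sum(abs(r - diag(diag(r))))
}

# best objective over symmetric 2x2 SPD matrices with equal diagonal, by a
# two-stage dense grid search over (diagonal, off-diagonal)
grid_search_2x2 <- function(r_hat, lam, tau, d_range = c(0.5, 1.6),
                            o_range = c(-0.95, 0.95)) {
  best <- c(NA, NA, Inf)
  dg <- seq(d_range[1], d_range[2], length.out = 81)
  og <- seq(o_range[1], o_range[2], length.out = 81)
  for (pass in 1:3) {
    for (dd in dg) for (oo in og) {
      if (dd <= abs(oo)) next  # not PD
      r <- matrix(c(dd, oo, oo, dd), 2, 2)
      val <- objective_oracle(r, r_hat, lam, tau)
      if (val < best[3]) best <- c(dd, oo, val)
    }
    hd <- diff(dg[1:2]); ho <- diff(og[1:2])
    dg <- seq(best[1] - hd, best[1] + hd, length.out = 41)
    og <- seq(best[2] - ho, best[2] + ho, length.out = 41)
  }
  list(diag = best[1], off = best[2], objective = best[3])
}

# best objective over 3x3 SPD matrices via multi-start BFGS on the Cholesky
# parameterization (an independent numeric search, not the package solver)
optim_search_3x3 <- function(r_hat, lam, tau, n_starts = 8, seed = 1) {
  obj_theta <- function(theta) {
    L <- matrix(0, 3, 3)
    L[lower.tri(L, diag = TRUE)] <- theta
    diag(L) <- exp(diag(L))  # keep strictly PD
    r <- L %*% t(L)
    objective_oracle(r, r_hat, lam, tau)
  }
  best <- Inf
  withr::with_seed(seed, {
    starts <- replicate(n_starts, rnorm(6, sd = 0.3), simplify = FALSE)
    starts[[1]] <- c(0, 0, 0, 0, 0, 0)  # identity start
    for (s in starts) {
      o <- tryCatch(stats::optim(s, obj_theta, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-14)),
                    error = function(e) NULL)
      if (!is.null(o) && o$value < best) best <- o$value
    }
  })
  best
}

# random correlation-like symmetric matrix from a small data draw
random_correlation <- function(d, n = 3 * d, seed = 1) {
  withr::with_seed(seed, stats::cor(matrix(rnorm(n * d), n, d)))
}
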