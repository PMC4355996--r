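#' Sample correlation matrix
#'
#' Computes the ordinary Pearson sample correlation matrix of a samples x
#' features matrix, refusing constant features (whose correlation is
#' undefined) with an informative error.
#'
#' @param x A numeric matrix or data frame with samples in rows and features
#'   in columns. At least two rows are required.
#' @return A `d x d` symmetric correlation matrix with unit diagonal.
#' @examples
#' sample_correlation(matrix(rnorm(40), 10, 4))
#' @export
sample_correlation <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric.", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 samples to estimate a correlation.", call. = FALSE)
  v <- .col_vars(x)
  bad <- which(v <= 0 | !is.finite(v))
  if (length(bad) > 0L) {
    stop("feature(s) with zero variance: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  }
  r <- stats::cor(x)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  (r + t(r)) / 2
}

# column-wise sample variances (n - 1 denominator) without forming apply() calls
.col_vars <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Penalized correlation objective
#'
#' Evaluates the criterion minimized by [solve_penalized_correlation()]:
#' half the squared Frobenius distance to the target `r_hat`, minus a
#' log-determinant barrier weighted by `tau`, plus an L1 penalty `lam` on the
#' off-diagonal entries only.
#'
#' @param r Symmetric positive definite matrix at which to evaluate.
#' @param r_hat Target (sample) correlation matrix, same dimension.
#' @param lam Non-negative L1 tuning parameter.
#' @param tau Positive log-determinant barrier weight.
#' @return A finite scalar.
#' @export
penalized_cor_objective <- function(r, r_hat, lam, tau) {
  r <- as.matrix(r)
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch)) stop("`r` must be positive definite (log-determinant undefined).", call. = FALSE)
  logdet <- 2 * sum(log(diag(ch)))
  sum((r - r_hat)^2) / 2 - tau * logdet + lam * .offdiag_l1(r)
}

.offdiag_l1 <- function(r) sum(abs(r)) - sum(abs(diag(r)))

# soft threshold off-diagonal entries by `by`, leave the diagonal alone
.soft_offdiag <- function(m, by) {
  d <- diag(m)
  m <- sign(m) * pmax(abs(m) - by, 0)
  diag(m) <- d
  m
}

#' Sparse positive definite correlation estimation
#'
#' Minimizes `||R - R_hat||_F^2 / 2 - tau * log|R| + lam * |R^-|_1` over
#' positive definite matrices `R`, where `|R^-|_1` is the L1 norm of the
#' off-diagonal entries. The log-determinant barrier keeps every iterate
#' (and the solution) strictly positive definite while the L1 term zeroes
#' weak off-diagonal correlations exactly.
#'
#' The solver is a monotone proximal-gradient scheme: the smooth part
#' (Frobenius + barrier) is linearized, the L1 part handled by
#' soft-thresholding the off-diagonals, and a backtracking line search
#' guarantees a non-increasing objective and positive definite iterates.
#' At `lam = 0` the minimizer has a closed form in the eigenbasis of
#' `r_hat`: each eigenvalue `e` maps to `(e + sqrt(e^2 + 4 tau)) / 2`; that
#' solution also initializes the iterations for `lam > 0`.
#'
#' @param r_hat Symmetric matrix to shrink towards (typically a sample
#'   correlation matrix).
#' @param lam Non-negative L1 tuning parameter; larger values give sparser
#'   off-diagonals.
#' @param tau Positive log-determinant barrier weight. The default `1e-4` is
#'   small enough to leave well-conditioned inputs essentially unchanged.
#' @param max_iter Maximum number of proximal-gradient iterations.
#' @param tol Convergence tolerance on both the maximum entrywise change
#'   between iterates and the relative objective change.
#' @param zero_tol Off-diagonal magnitudes below this are stored as exact
#'   zeros so sparsity patterns are well defined.
#' @param init Optional symmetric positive definite warm start (e.g. the
#'   solution at a nearby `lam`).
#' @return An object of class `sparse_cor_fit`: a list with elements
#'   `r_hat`, `r_tilde` (the estimate), `lam`, `tau`, `n_iter`, `converged`,
#'   `objective` and `stationarity` (max-norm of a minimal subgradient).
#' @seealso [correlation_to_covariance()] to rescale to a covariance.
#' @examples
#' r <- sample_correlation(matrix(rnorm(200), 20, 10))
#' fit <- solve_penalized_correlation(r, lam = 0.3)
#' sum(fit$r_tilde[upper.tri(fit$r_tilde)] == 0)
#' @export
solve_penalized_correlation <- function(r_hat, lam, tau = 1e-4,
                                        max_iter = 1000L, tol = 1e-7,
                                        zero_tol = 1e-10, init = NULL) {
  r_hat <- as.matrix(r_hat)
  d <- nrow(r_hat)
  if (ncol(r_hat) != d) stop("`r_hat` must be square.", call. = FALSE)
  if (max(abs(r_hat - t(r_hat))) > 1e-8) {
    stop("`r_hat` must be symmetric.", call. = FALSE)
  }
  if (lam < 0) stop("`lam` must be >= 0.", call. = FALSE)
  if (tau <= 0) stop("`tau` must be > 0.", call. = FALSE)
  r_hat <- (r_hat + t(r_hat)) / 2

  done <- function(r, n_iter, converged) {
    r[abs(r) < zero_tol & row(r) != col(r)] <- 0
    r <- (r + t(r)) / 2
    structure(
      list(r_hat = r_hat, r_tilde = r, lam = lam, tau = tau,
           n_iter = n_iter, converged = converged,
           objective = penalized_cor_objective(r, r_hat, lam, tau),
           stationarity = .stationarity(r, r_hat, lam, tau)),
      class = "sparse_cor_fit")
  }

  if (d == 1L) {
    e <- r_hat[1, 1]
    return(done(matrix((e + sqrt(e^2 + 4 * tau)) / 2, 1, 1), 0L, TRUE))
  }

  # lam = 0 closed form / warm start: solve R - R_hat - tau R^-1 = 0 in the
  # eigenbasis of r_hat (positive root of x^2 - e x - tau = 0)
  eg <- eigen(r_hat, symmetric = TRUE)
  phi <- (eg$values + sqrt(eg$values^2 + 4 * tau)) / 2
  r0 <- eg$vectors %*% (phi * t(eg$vectors))
  r0 <- (r0 + t(r0)) / 2
  if (lam == 0) return(done(r0, 0L, TRUE))

  if (!is.null(init)) {
    init <- (as.matrix(init) + t(as.matrix(init))) / 2
    if (!is.null(tryCatch(chol(init), error = function(e) NULL))) r0 <- init
  }

  res <- .solve_pencor_cpp(r_hat, r0, lam, tau, as.integer(max_iter), tol)
  if (!res$converged) {
    warning("penalized correlation solver did not converge in ",
            max_iter, " iterations (lam = ", lam, ").", call. = FALSE)
  }
  done(res$r, res$n_iter, res$converged)
}

# max-norm of the minimal subgradient of the objective at r
.stationarity <- function(r, r_hat, lam, tau) {
  g <- r - r_hat - tau * chol2inv(chol(r))
  off <- row(r) != col(r)
  res <- abs(g)
  nz <- off & r != 0
  res[nz] <- abs(g[nz] + lam * sign(r[nz]))
  z <- off & r == 0
  res[z] <- pmax(abs(g[z]) - lam, 0)
  max(res)
}

#' @export
print.sparse_cor_fit <- function(x, ...) {
  d <- nrow(x$r_tilde)
  nz <- sum(x$r_tilde[upper.tri(x$r_tilde)] != 0)
  cat("Sparse positive definite correlation estimate\n")
  cat(sprintf("  dimension: %d x %d   lam: %g   tau: %g\n", d, d, x$lam, x$tau))
  cat(sprintf("  nonzero off-diagonal pairs: %d of %d\n", nz, d * (d - 1) / 2))
  cat(sprintf("  iterations: %d   converged: %s   objective: %.6g\n",
              x$n_iter, x$converged, x$objective))
  invisible(x)
}

#' Rescale a correlation estimate to the covariance scale
#'
#' Maps an estimated correlation matrix back to the original measurement
#' scale via `sigma = D^{1/2} R D^{1/2}` with `D = diag(variances)`. Zero
#' entries of the correlation estimate stay exactly zero.
#'
#' @param sol A `sparse_cor_fit` object (or a bare correlation matrix).
#' @param variances Strictly positive vector of sample variances, one per
#'   feature.
#' @return An object of class `cov_estimate`: list with `sigma` (the
#'   covariance matrix) and `variances`.
#' @export
correlation_to_covariance <- function(sol, variances) {
  r <- if (inherits(sol, "sparse_cor_fit")) sol$r_tilde else as.matrix(sol)
  if (any(variances <= 0) || any(!is.finite(variances))) {
    stop("`variances` must be strictly positive and finite.", call. = FALSE)
  }
  if (length(variances) != nrow(r)) {
    stop("`variances` length must match the matrix dimension.", call. = FALSE)
  }
  s <- sqrt(variances)
  sigma <- r * tcrossprod(s)
  structure(list(sigma = sigma, variances = variances), class = "cov_estimate")
}

# one-call convenience: sparse covariance of one class's block of data
.sparse_block_cov <- function(x, lam, tau = 1e-4, ...) {
  v <- .col_vars(x)
  bad <- which(v <= 0 | !is.finite(v))
  if (length(bad) > 0L) {
    stop("feature(s) with zero variance: ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  sol <- solve_penalized_correlation(sample_correlation(x), lam = lam, tau = tau, ...)
  correlation_to_covariance(sol, v)$sigma
}
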