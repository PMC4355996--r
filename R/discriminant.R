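#' Gaussian class-conditional model
#'
#' Internal constructor shared by all discriminant rules. Each class `k`
#' carries a mean vector and a covariance, which may be stored dense, as a
#' vector of variances (diagonal rules), or as a list of per-block matrices
#' realizing a block-diagonal covariance. Cholesky factors and
#' log-determinants are precomputed so density evaluation only needs
#' triangular solves.
#'
#' @param labels Character vector of class labels, in priority (tie-break)
#'   order.
#' @param means `K x p` matrix of class means.
#' @param covs For `kind = "dense"` a list of `p x p` matrices (or one if
#'   `shared`); for `"diagonal"` a list of variance vectors; for `"blocks"`
#'   a list (per class) of lists of block matrices.
#' @param kind One of `"dense"`, `"diagonal"`, `"blocks"`.
#' @param shared If `TRUE` a single covariance is used for every class
#'   (LDA-type model).
#' @param blocks For `kind = "blocks"`, a list of integer vectors giving the
#'   column indices (into the model's feature space) of each block.
#' @return An object of class `cg_model`.
#' @keywords internal
new_cg_model <- function(labels, means, covs, kind, shared, blocks = NULL) {
  kind <- match.arg(kind, c("dense", "diagonal", "blocks"))
  K <- length(labels)
  p <- ncol(means)
  if (nrow(means) != K) stop("`means` must have one row per class.", call. = FALSE)
  if (kind == "blocks") {
    if (sum(lengths(blocks)) != p) {
      stop("block index vectors must cover all ", p, " features.", call. = FALSE)
    }
  }
  get_cov <- function(k) if (shared) covs[[1L]] else covs[[k]]
  chols <- vector("list", K)
  logdets <- numeric(K)
  for (k in seq_len(K)) {
    ck <- get_cov(k)
    if (kind == "diagonal") {
      if (any(ck <= 0)) stop("non-positive variance in class ", labels[k], ".", call. = FALSE)
      chols[[k]] <- sqrt(ck)
      logdets[k] <- sum(log(ck))
    } else if (kind == "dense") {
      ch <- tryCatch(chol(ck), error = function(e) NULL)
      if (is.null(ch)) {
        stop("covariance for class ", labels[k], " is singular; ",
             "use the diagonal (fit_dlda/fit_dqda) or sparse (sqda) variants.",
             call. = FALSE)
      }
      chols[[k]] <- ch
      logdets[k] <- 2 * sum(log(diag(ch)))
    } else {
      ch_b <- lapply(ck, function(b) {
        ch <- tryCatch(chol(b), error = function(e) NULL)
        if (is.null(ch)) stop("a covariance block for class ", labels[k],
                              " is not positive definite.", call. = FALSE)
        ch
      })
      chols[[k]] <- ch_b
      logdets[k] <- sum(vapply(ch_b, function(ch) 2 * sum(log(diag(ch))), 0))
    }
    if (shared && k == 1L) {
      chols <- rep(chols[1L], K)
      logdets <- rep(logdets[1L], K)
      break
    }
  }
  structure(
    list(labels = labels, means = means, covs = covs, kind = kind,
         shared = shared, blocks = blocks, chols = chols, logdets = logdets,
         p = p),
    class = "cg_model")
}

# n x K matrix of per-class Gaussian log-densities
.cg_log_densities <- function(model, x) {
  x <- .as_feature_matrix(x, model$p)
  n <- nrow(x)
  K <- length(model$labels)
  out <- matrix(0, n, K, dimnames = list(NULL, model$labels))
  for (k in seq_len(K)) {
    ctr <- x - matrix(model$means[k, ], n, model$p, byrow = TRUE)
    if (model$kind == "diagonal") {
      quad <- colSums((t(ctr) / model$chols[[k]])^2)
    } else if (model$kind == "dense") {
      z <- backsolve(model$chols[[k]], t(ctr), transpose = TRUE)
      quad <- colSums(z^2)
    } else {
      quad <- numeric(n)
      for (b in seq_along(model$blocks)) {
        z <- backsolve(model$chols[[k]][[b]], t(ctr[, model$blocks[[b]], drop = FALSE]),
                       transpose = TRUE)
        quad <- quad + colSums(z^2)
      }
    }
    out[, k] <- -0.5 * (model$p * log(2 * pi) + model$logdets[k] + quad)
  }
  out
}

.as_feature_matrix <- function(x, p) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != p) {
    stop("expected ", p, " features, got ", ncol(x), ".", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Gaussian log-density under a fitted class model
#'
#' Evaluates the multivariate normal log-density of observation(s) `x` under
#' class `k` of a fitted model. For block-diagonal covariances the density
#' factorizes over blocks: the log-determinant is the sum of per-block
#' log-determinants and the quadratic form decomposes blockwise, so the
#' value is identical to evaluating the assembled dense covariance.
#'
#' @param model A `cg_model` as returned by the `fit_*` functions.
#' @param k Class index (position in `model$labels`).
#' @param x A feature vector or matrix of rows to evaluate.
#' @return Numeric vector of log-densities, one per row of `x`.
#' @export
log_density <- function(model, k, x) {
  stopifnot(inherits(model, "cg_model"))
  if (k < 1L || k > length(model$labels)) stop("invalid class index.", call. = FALSE)
  unname(.cg_log_densities(model, x)[, k])
}

#' Maximum-likelihood classification
#'
#' Assigns each row of `x` to the class maximizing the Gaussian log-density.
#' The rule is pure maximum likelihood: no prior or class-frequency term is
#' added, so balanced and unbalanced training sets are scored identically.
#' Ties are broken deterministically in favour of the earliest class label.
#'
#' @inheritParams log_density
#' @param x Matrix or data frame of observations (samples in rows).
#' @return Factor of predicted class labels with levels `model$labels`.
#' @export
classify_ml <- function(model, x) {
  stopifnot(inherits(model, "cg_model"))
  scores <- .cg_log_densities(model, x)
  idx <- max.col(scores, ties.method = "first")
  factor(model$labels[idx], levels = model$labels)
}

#' @export
predict.cg_model <- function(object, newdata, ...) classify_ml(object, newdata)

#' @export
print.cg_model <- function(x, ...) {
  cat(sprintf("Gaussian discriminant model (%s covariance%s)\n",
              x$kind, if (x$shared) ", shared across classes" else ", per class"))
  cat(sprintf("  classes: %s\n", paste(x$labels, collapse = ", ")))
  cat(sprintf("  features: %d\n", x$p))
  invisible(x)
}


# K x p matrix of class means (robust to p = 1)
.class_means <- function(x, idx) {
  p <- ncol(x)
  m <- matrix(0, length(idx), p)
  for (k in seq_along(idx)) m[k, ] <- colMeans(x[idx[[k]], , drop = FALSE])
  m
}

# split a labeled matrix into per-class row index lists, validating counts
.class_split <- function(y, min_per_class = 2L) {
  y <- as.factor(y)
  y <- droplevels(y)
  idx <- split(seq_along(y), y)
  small <- names(idx)[lengths(idx) < min_per_class]
  if (length(small) > 0L) {
    stop("class(es) with fewer than ", min_per_class, " samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  idx
}

#' Fit classical discriminant models
#'
#' `fit_lda()` fits a linear discriminant model with a single pooled
#' within-class covariance matrix; `fit_qda()` a quadratic model with one
#' dense covariance per class. These dense fits require more samples than
#' features and exist mainly for small problems and as oracles; in the
#' large-p small-n regime use the diagonal (`fit_dlda()`, `fit_dqda()`) or
#' sparse ([sqda()]) variants.
#'
#' @param x Samples x features matrix or data frame.
#' @param y Class labels (coercible to factor); each class needs at least
#'   two samples.
#' @return A `cg_model`.
#' @export
fit_lda <- function(x, y) {
  x <- as.matrix(x)
  idx <- .class_split(y)
  K <- length(idx)
  p <- ncol(x)
  n <- nrow(x)
  if (n - K < p) {
    stop("pooled covariance is singular when n - K < p (", n - K, " < ", p,
         "); use fit_dlda/fit_dqda or sqda.", call. = FALSE)
  }
  means <- .class_means(x, idx)
  pooled <- matrix(0, p, p)
  for (k in seq_len(K)) {
    xc <- x[idx[[k]], , drop = FALSE]
    xc <- sweep(xc, 2L, means[k, ])
    pooled <- pooled + crossprod(xc)
  }
  pooled <- pooled / (n - K)
  new_cg_model(names(idx), means, list(pooled), kind = "dense", shared = TRUE)
}

#' @rdname fit_lda
#' @export
fit_qda <- function(x, y) {
  x <- as.matrix(x)
  idx <- .class_split(y)
  p <- ncol(x)
  nk <- lengths(idx)
  if (any(nk <= p)) {
    stop("per-class covariance is singular when n_k <= p; ",
         "use fit_dlda/fit_dqda or sqda.", call. = FALSE)
  }
  means <- .class_means(x, idx)
  covs <- lapply(idx, function(i) stats::cov(x[i, , drop = FALSE]))
  new_cg_model(names(idx), means, unname(covs), kind = "dense", shared = FALSE)
}

#' Diagonal discriminant rules
#'
#' `fit_dlda()` uses one pooled within-class variance per feature (diagonal
#' LDA); `fit_dqda()` uses per-class per-feature variances (diagonal QDA).
#' Variances use the unbiased estimator: `n_k - 1` per class, and the pooled
#' variance divides by the summed within-class degrees of freedom.
#'
#' @inheritParams fit_lda
#' @return A `cg_model` with diagonal covariance structure.
#' @export
fit_dlda <- function(x, y) {
  x <- as.matrix(x)
  idx <- .class_split(y)
  p <- ncol(x)
  means <- .class_means(x, idx)
  ss <- matrix(0, length(idx), p)
  for (k in seq_along(idx)) {
    xc <- sweep(x[idx[[k]], , drop = FALSE], 2L, means[k, ])
    ss[k, ] <- colSums(xc^2)
  }
  pooled <- colSums(ss) / (nrow(x) - length(idx))
  bad <- which(pooled <= 0)
  if (length(bad) > 0L) {
    stop("zero pooled variance for feature(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  new_cg_model(names(idx), means, list(pooled), kind = "diagonal", shared = TRUE)
}

#' @rdname fit_dlda
#' @export
fit_dqda <- function(x, y) {
  x <- as.matrix(x)
  idx <- .class_split(y)
  p <- ncol(x)
  means <- .class_means(x, idx)
  covs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    v <- .col_vars(x[idx[[k]], , drop = FALSE])
    bad <- which(v <= 0)
    if (length(bad) > 0L) {
      stop("zero variance in class ", names(idx)[k], " for feature(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    covs[[k]] <- v
  }
  new_cg_model(names(idx), means, covs, kind = "diagonal", shared = FALSE)
}
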