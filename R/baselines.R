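#' Shrunken-centroids regularized discriminant analysis
#'
#' Fits SCRDA: the pooled within-class covariance is shrunk towards the
#' identity, `Sigma~ = alpha * Sigma^ + (1 - alpha) * I` (or the analogous
#' shrinkage of the correlation matrix when `shrink_target = "correlation"`),
#' and the transformed centroids `x*_k = Sigma~^{-1} x_k` are soft-thresholded
#' componentwise at `delta`. The discriminant score for class `k` at a test
#' point `x` is `x' x*_k - x_k' x*_k / 2` with equal priors, which reduces to
#' the linear discriminant rule at `alpha = 1, delta = 0`.
#'
#' The pair `(alpha, delta)` is tuned by stratified cross-validation; among
#' pairs tied on cross-validation error the MIN-MIN rule keeps the most
#' parsimonious model (fewest nonzero shrunken score components, then the
#' larger `delta`, then the smaller `alpha`).
#'
#' @param data Samples x features data frame or matrix.
#' @param labels Class labels, coercible to factor.
#' @param alpha_grid Candidate shrinkage weights in `[0, 1]`.
#' @param delta_grid Candidate soft thresholds, `>= 0`.
#' @param folds Stratified cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @param shrink_target Shrink the covariance (default) or the correlation
#'   matrix.
#' @return An object of class `scrda_fit`: chosen `alpha` and `delta`, the
#'   shrunken score matrix `scores` (features x classes), class means, the
#'   Cholesky factor of the shrunk covariance (for the nearest-centroid
#'   fallback), the cross-validation table `cv`, and `n_features` (features
#'   with a nonzero score in any class).
#' @export
scrda <- function(data, labels,
                  alpha_grid = c(0, 0.25, 0.5, 0.75, 0.99),
                  delta_grid = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                  folds = 5L, seed = 1L,
                  shrink_target = c("covariance", "correlation")) {
  shrink_target <- match.arg(shrink_target)
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  y <- droplevels(as.factor(labels))
  if (any(alpha_grid < 0 | alpha_grid > 1)) stop("`alpha_grid` must be within [0, 1].", call. = FALSE)
  if (any(delta_grid < 0)) stop("`delta_grid` must be >= 0.", call. = FALSE)
  fold_id <- .stratified_folds(y, folds, seed)

  grid <- expand.grid(alpha = alpha_grid, delta = delta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  wrong <- numeric(nrow(grid))
  for (f in seq_len(max(fold_id))) {
    tr <- fold_id != f
    parts <- .scrda_parts(x[tr, , drop = FALSE], y[tr], shrink_target)
    for (a in alpha_grid) {
      sc0 <- .scrda_scores(parts, a)  # unshrunk Sigma~^{-1} x_k per alpha
      for (j in which(grid$alpha == a)) {
        pred <- .scrda_classify(x[!tr, , drop = FALSE], parts$means,
                                sc0, grid$delta[j])
        wrong[j] <- wrong[j] + sum(pred != as.integer(y[!tr]))
      }
    }
  }
  cv <- tibble::tibble(alpha = grid$alpha, delta = grid$delta,
                       cv_error = wrong / length(y))

  # MIN-MIN: minimal CV error, then fewest nonzero score components on the
  # full training data, then larger delta, then smaller alpha
  parts_full <- .scrda_parts(x, y, shrink_target)
  best <- which(cv$cv_error == min(cv$cv_error))
  nz <- vapply(best, function(j) {
    sc <- .soft_matrix(.scrda_scores(parts_full, cv$alpha[j]), cv$delta[j])
    sum(rowSums(sc != 0) > 0)
  }, 0L)
  ord <- order(nz, -cv$delta[best], cv$alpha[best])
  pick <- best[ord[1L]]
  alpha <- cv$alpha[pick]; delta <- cv$delta[pick]

  sc0 <- .scrda_scores(parts_full, alpha)
  scores <- .soft_matrix(sc0, delta)
  all_zero <- all(scores == 0)
  if (all_zero) {
    warning("all shrunken scores are zero; falling back to nearest centroid ",
            "in the shrunk-covariance metric.", call. = FALSE)
  }
  structure(
    list(alpha = alpha, delta = delta, scores = scores,
         means = parts_full$means, labels = levels(y),
         chol_sigma = chol(.scrda_sigma(parts_full, alpha)),
         all_zero = all_zero, cv = cv,
         n_features = sum(rowSums(scores != 0) > 0),
         shrink_target = shrink_target),
    class = "scrda_fit")
}

# pooled within-class pieces reused across the alpha grid
.scrda_parts <- function(x, y, shrink_target) {
  idx <- .class_split(y)
  p <- ncol(x)
  means <- .class_means(x, idx)
  pooled <- matrix(0, p, p)
  for (k in seq_along(idx)) {
    xc <- sweep(x[idx[[k]], , drop = FALSE], 2L, means[k, ])
    pooled <- pooled + crossprod(xc)
  }
  pooled <- pooled / max(1L, nrow(x) - length(idx))
  list(means = means, pooled = pooled, labels = names(idx),
       shrink_target = shrink_target)
}

.scrda_sigma <- function(parts, alpha) {
  p <- ncol(parts$pooled)
  if (parts$shrink_target == "covariance") {
    sig <- alpha * parts$pooled
    diag(sig) <- diag(sig) + (1 - alpha)
    sig
  } else {
    v <- pmax(diag(parts$pooled), .Machine$double.eps)
    s <- sqrt(v)
    r <- parts$pooled / tcrossprod(s)
    r <- alpha * r
    diag(r) <- diag(r) + (1 - alpha)
    r * tcrossprod(s)
  }
}

# features x classes matrix Sigma~^{-1} x_k (before soft thresholding)
.scrda_scores <- function(parts, alpha) {
  sig <- .scrda_sigma(parts, alpha)
  ch <- chol(sig)
  backsolve(ch, backsolve(ch, t(parts$means), transpose = TRUE))
}

.soft_matrix <- function(m, delta) sign(m) * pmax(abs(m) - delta, 0)

# integer class assignments from shrunken scores (ties -> earliest class)
.scrda_classify <- function(x, means, sc0, delta) {
  sc <- .soft_matrix(sc0, delta)
  d <- x %*% sc - matrix(colSums(t(means) * sc) / 2, nrow(x), ncol(sc),
                         byrow = TRUE)
  max.col(d, ties.method = "first")
}

#' @export
predict.scrda_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (object$all_zero) {
    # nearest centroid in the Sigma~ metric
    d <- vapply(seq_along(object$labels), function(k) {
      ctr <- sweep(x, 2L, object$means[k, ])
      z <- backsolve(object$chol_sigma, t(ctr), transpose = TRUE)
      colSums(z^2)
    }, numeric(nrow(x)))
    d <- matrix(d, nrow = nrow(x))
    idx <- max.col(-d, ties.method = "first")
  } else {
    d <- x %*% object$scores -
      matrix(colSums(t(object$means) * object$scores) / 2,
             nrow(x), length(object$labels), byrow = TRUE)
    idx <- max.col(d, ties.method = "first")
  }
  factor(object$labels[idx], levels = object$labels)
}

#' @export
print.scrda_fit <- function(x, ...) {
  cat("Shrunken-centroids regularized discriminant fit\n")
  cat(sprintf("  alpha = %g, delta = %g (%s shrinkage)\n",
              x$alpha, x$delta, x$shrink_target))
  cat(sprintf("  features with nonzero scores: %d\n", x$n_features))
  invisible(x)
}

#' @export
tidy.scrda_fit <- function(x, ...) x$cv

#' @export
glance.scrda_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, delta = x$delta,
                 n_features = x$n_features,
                 cv_error = min(x$cv$cv_error))
}

#' k-nearest-neighbour classification
#'
#' Classifies each test sample by the majority vote of its `h` nearest
#' training samples in Euclidean distance. Vote ties are resolved in favour
#' of the tied class containing the single nearest neighbour, so the rule
#' is deterministic.
#'
#' @param train Training samples x features matrix or data frame.
#' @param labels Training class labels.
#' @param test Test samples x features matrix or data frame.
#' @param h Number of neighbours (default 3).
#' @return Factor of predicted labels.
#' @export
nn_classify <- function(train, labels, test, h = 3L) {
  xtr <- as.matrix(train); xte <- as.matrix(test)
  y <- droplevels(as.factor(labels))
  h <- as.integer(h)
  if (h < 1L || h > nrow(xtr)) stop("`h` must be between 1 and the number of training samples.", call. = FALSE)
  if (ncol(xtr) != ncol(xte)) stop("train and test dimension mismatch.", call. = FALSE)
  # squared distances via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * tcrossprod(xte, xtr)
  lv <- levels(y)
  out <- integer(nrow(xte))
  yi <- as.integer(y)
  for (i in seq_len(nrow(xte))) {
    nb <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(h)]
    votes <- tabulate(yi[nb], nbins = length(lv))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      # first neighbour whose class is among the tied ones decides
      top <- yi[nb[match(TRUE, yi[nb] %in% top)]]
    }
    out[i] <- top
  }
  factor(lv[out], levels = lv)
}

#' Tune the number of top-ranked genes by cross-validation
#'
#' Ranks features by absolute two-sample t statistic (binary labels) or
#' one-way ANOVA F statistic (more classes) once on the full training set
#' and, for each candidate count `m`, estimates the misclassification error
#' of the requested rule fitted on the top `m` features by stratified
#' cross-validation. Returns the count with minimal error, ties going to
#' the smallest count. Because the ranking is not refit within folds, the
#' cross-validation errors are optimistic for small counts; this matches
#' the classical screening protocol this comparator reproduces.
#'
#' @param data Samples x features data frame or matrix.
#' @param labels Class labels.
#' @param method Classification rule to tune: `"dlda"`, `"dqda"`, or
#'   `"nn"`.
#' @param counts Candidate gene counts (default 50 to 2000 by 50). Values
#'   exceeding the number of features are dropped with a warning.
#' @param folds Stratified cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @param h Neighbours for `method = "nn"`.
#' @return A list with `count` (the chosen size) and `cv` (a tibble of
#'   count vs cross-validation error).
#' @export
top_gene_cv_screen <- function(data, labels, method = c("dlda", "dqda", "nn"),
                               counts = seq(50L, 2000L, by = 50L),
                               folds = 5L, seed = 1L, h = 3L) {
  method <- match.arg(method)
  x <- as.matrix(data)
  y <- droplevels(as.factor(labels))
  counts <- sort(unique(as.integer(counts)))
  if (any(counts > ncol(x))) {
    warning("dropping candidate counts larger than the number of features (",
            ncol(x), ").", call. = FALSE)
    counts <- counts[counts <= ncol(x)]
  }
  if (length(counts) == 0L) stop("no valid candidate counts.", call. = FALSE)
  fold_id <- .stratified_folds(y, folds, seed)
  stat <- if (nlevels(y) == 2L) two_sample_t(x, y) else .anova_f(x, y)
  ord <- .rank_features(stat)
  wrong <- numeric(length(counts))
  for (f in seq_len(max(fold_id))) {
    tr <- fold_id != f
    for (j in seq_along(counts)) {
      feat <- ord[seq_len(counts[j])]
      pred <- .fit_predict_rule(method, x[tr, feat, drop = FALSE], y[tr],
                                x[!tr, feat, drop = FALSE], h)
      wrong[j] <- wrong[j] + sum(pred != y[!tr])
    }
  }
  cv <- tibble::tibble(count = counts, cv_error = wrong / length(y))
  list(count = counts[which.min(cv$cv_error)], cv = cv)
}

.fit_predict_rule <- function(method, xtr, ytr, xte, h = 3L) {
  switch(method,
    "dlda" = classify_ml(fit_dlda(xtr, ytr), xte),
    "dqda" = classify_ml(fit_dqda(xtr, ytr), xte),
    "nn" = nn_classify(xtr, ytr, xte, h = h)
  )
}
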