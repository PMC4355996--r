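#' Pooled two-sample t statistics per feature
#'
#' Computes, for every feature, the two-sample t statistic with pooled
#' variance between the two classes (first factor level minus second).
#' Features with zero pooled variance are an error, since their statistic is
#' undefined.
#'
#' @param x Samples x features matrix or data frame.
#' @param y Binary class labels; each class needs at least two samples.
#' @return Numeric vector of t statistics, one per feature.
#' @examples
#' two_sample_t(rbind(matrix(1:3), matrix(4:6)), rep(c("a", "b"), each = 3))
#' @export
two_sample_t <- function(x, y) {
  x <- as.matrix(x)
  idx <- .class_split(y)
  if (length(idx) != 2L) stop("`y` must have exactly two classes.", call. = FALSE)
  n1 <- length(idx[[1L]]); n2 <- length(idx[[2L]])
  x1 <- x[idx[[1L]], , drop = FALSE]; x2 <- x[idx[[2L]], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(x1^2) - n1 * m1^2
  ss2 <- colSums(x2^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  bad <- which(sp2 <= 0)
  if (length(bad) > 0L) {
    stop("zero pooled variance for feature(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# one-way ANOVA F statistics per feature (multi-class feature ranking)
.anova_f <- function(x, y) {
  x <- as.matrix(x)
  idx <- .class_split(y)
  K <- length(idx)
  n <- nrow(x)
  gm <- colMeans(x)
  between <- 0; within <- 0
  for (k in seq_len(K)) {
    xk <- x[idx[[k]], , drop = FALSE]
    mk <- colMeans(xk)
    between <- between + length(idx[[k]]) * (mk - gm)^2
    within <- within + colSums(sweep(xk, 2L, mk)^2)
  }
  (between / (K - 1)) / (within / (n - K))
}

# |t| descending, ties broken by the lower original feature index
.rank_features <- function(stat) order(-abs(stat), seq_along(stat))

#' Partition ranked features into equal-size blocks
#'
#' Sorts features by absolute t statistic (descending, ties to the lower
#' original index) and groups consecutive runs of `block_size` features into
#' blocks, from the most to the least discriminating. Trailing features that
#' do not fill a complete block are dropped; by construction they are the
#' least informative under the ranking.
#'
#' @param t_stats Per-feature statistics used for ordering (typically from
#'   [two_sample_t()]).
#' @param block_size Number of features per block.
#' @return A `block_layout`: list with `feature_order` (the ranked original
#'   indices actually retained), `block_size`, `n_blocks`, `blocks` (list of
#'   original-index vectors), and `selected`/`cv_error` slots filled by
#'   [select_blocks()].
#' @export
make_blocks <- function(t_stats, block_size) {
  p <- length(t_stats)
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("`block_size` must be >= 1.", call. = FALSE)
  if (block_size > p) stop("`block_size` (", block_size, ") exceeds the number of features (", p, ").", call. = FALSE)
  ord <- .rank_features(t_stats)
  n_blocks <- p %/% block_size
  keep <- ord[seq_len(n_blocks * block_size)]
  blocks <- split(keep, rep(seq_len(n_blocks), each = block_size))
  structure(
    list(feature_order = keep, block_size = block_size, n_blocks = n_blocks,
         blocks = unname(blocks), selected = rep(NA, n_blocks),
         cv_error = rep(NA_real_, n_blocks)),
    class = "block_layout")
}

#' @export
print.block_layout <- function(x, ...) {
  cat(sprintf("Block layout: %d blocks of %d features (%d features retained)\n",
              x$n_blocks, x$block_size, length(x$feature_order)))
  if (!anyNA(x$selected)) {
    cat(sprintf("  selected blocks: %s\n",
                paste(which(x$selected), collapse = ", ")))
  }
  invisible(x)
}

# stratified fold assignment: a fold id per sample, balanced within class
.stratified_folds <- function(y, folds, seed) {
  idx <- split(seq_along(y), as.factor(y))
  small <- names(idx)[lengths(idx) < folds]
  if (length(small) > 0L) {
    stop("class(es) with fewer samples than folds (", folds, "): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  fold_id <- integer(length(y))
  withr::with_seed(seed, {
    for (i in idx) fold_id[i] <- sample(rep_len(seq_len(folds), length(i)))
  })
  fold_id
}

# fit a Gaussian model on one block of features with the requested
# estimator; cross-validation refits silence the solver's non-convergence
# warning (the returned iterate is still used to score the block)
.fit_block_model <- function(x, y, estimator, lam, tau, quiet = FALSE) {
  switch(estimator,
    "sparse" = {
      idx <- .class_split(y)
      p <- ncol(x)
      means <- .class_means(x, idx)
      covs <- lapply(idx, function(i) {
        fit1 <- function() .sparse_block_cov(x[i, , drop = FALSE], lam = lam,
                                             tau = tau)
        if (quiet) suppressWarnings(fit1()) else fit1()
      })
      new_cg_model(names(idx), means, unname(covs), kind = "dense", shared = FALSE)
    },
    "diagonal-common" = fit_dlda(x, y),
    "diagonal-perclass" = fit_dqda(x, y)
  )
}

# cross-validated misclassification over a lambda grid for one block,
# computing each fold's per-class correlation once and warm-starting the
# solver along the (descending) grid
.tune_block_lambda <- function(x, y, features, fold_id, lambda_grid, tau) {
  folds <- max(fold_id)
  wrong <- numeric(length(lambda_grid))  # grid is sorted ascending
  ord <- rev(seq_along(lambda_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    xtr <- x[tr, features, drop = FALSE]
    idx <- .class_split(y[tr])
    means <- .class_means(xtr, idx)
    parts <- lapply(idx, function(i) {
      xb <- xtr[i, , drop = FALSE]
      list(r = sample_correlation(xb), v = .col_vars(xb))
    })
    xv <- x[!tr, features, drop = FALSE]
    yv <- y[!tr]
    init <- vector("list", length(idx))
    for (j in ord) {
      covs <- vector("list", length(idx))
      for (k in seq_along(idx)) {
        sol <- suppressWarnings(
          solve_penalized_correlation(parts[[k]]$r, lambda_grid[j],
                                      tau = tau, init = init[[k]]))
        init[[k]] <- sol$r_tilde
        covs[[k]] <- correlation_to_covariance(sol, parts[[k]]$v)$sigma
      }
      m <- new_cg_model(names(idx), means, covs, kind = "dense", shared = FALSE)
      wrong[j] <- wrong[j] + sum(classify_ml(m, xv) != yv)
    }
  }
  lambda_grid[which.min(wrong)]  # ties: smallest lambda
}

# per-block cross-validated misclassification error
.block_cv_error <- function(x, y, features, fold_id, estimator, lam, tau) {
  folds <- max(fold_id)
  wrong <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    m <- .fit_block_model(x[tr, features, drop = FALSE], y[tr],
                          estimator, lam, tau, quiet = TRUE)
    pred <- classify_ml(m, x[!tr, features, drop = FALSE])
    wrong <- wrong + sum(pred != y[!tr])
  }
  wrong / length(y)
}

#' Variable selection by blocks
#'
#' Scores every block of a [make_blocks()] layout by stratified
#' cross-validated misclassification of a per-block Gaussian rule fitted on
#' that block's features alone, then marks as selected all blocks whose
#' error is within `error_margin` of the smallest block error. The block
#' attaining the minimum is always selected.
#'
#' For the sparse estimator the per-class covariance of each block is the
#' penalized correlation estimate at the fixed screening sparsity
#' `screening_lambda`, rescaled by sample variances; the diagonal estimator
#' kinds reproduce the DLDA2/DQDA2 selection paths.
#'
#' @param x Samples x features matrix or data frame (all original features).
#' @param y Class labels.
#' @param layout A `block_layout`.
#' @param error_margin Tolerance added to the best block error when
#'   selecting blocks, in `[0, 0.5]`.
#' @param folds Number of stratified cross-validation folds.
#' @param seed Integer seed controlling the fold assignment.
#' @param screening_lambda Sparsity parameter used for every block during
#'   selection.
#' @param estimator Covariance estimator used for the per-block rules.
#' @param tau Log-determinant barrier weight passed to the solver.
#' @return The layout with `selected` and `cv_error` filled in.
#' @export
select_blocks <- function(x, y, layout, error_margin = 0.05, folds = 5L,
                          seed = 1L, screening_lambda = 0.2,
                          estimator = c("sparse", "diagonal-common", "diagonal-perclass"),
                          tau = 1e-4) {
  stopifnot(inherits(layout, "block_layout"))
  estimator <- match.arg(estimator)
  if (error_margin < 0 || error_margin > 0.5) {
    stop("`error_margin` must be in [0, 0.5].", call. = FALSE)
  }
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  fold_id <- .stratified_folds(y, folds, seed)
  errs <- vapply(layout$blocks, function(features) {
    .block_cv_error(x, y, features, fold_id, estimator, screening_lambda, tau)
  }, 0)
  layout$cv_error <- errs
  layout$selected <- errs <= min(errs) + error_margin
  layout
}

#' Sparse quadratic discriminant analysis
#'
#' Fits the full SQDA pipeline: features are ranked by absolute two-sample
#' t statistic and cut into equal blocks ([make_blocks()]); blocks are
#' screened by per-block cross-validation at a fixed sparsity
#' (`screening_lambda`) and kept when within `error_margin` of the best
#' block ([select_blocks()]); for each retained block a sparsity level is
#' chosen from `lambda_grid` by the same cross-validation (shared across
#' classes, ties going to the smallest value); and the final classifier is
#' a quadratic discriminant rule whose per-class covariance is
#' block-diagonal, each block a penalized correlation estimate rescaled by
#' the class sample variances.
#'
#' `dlda2()` and `dqda2()` run the identical ranking and block-selection
#' path but replace the sparse covariance with the pooled-diagonal and
#' per-class-diagonal estimators; no sparsity tuning is involved.
#'
#' @param data Samples x features data frame or matrix.
#' @param labels Class labels, coercible to factor. With more than two
#'   classes, features are ranked by one-way ANOVA F statistics instead of
#'   t statistics.
#' @param block_size Features per block (default 100).
#' @param error_margin Block-selection tolerance (default 0.05).
#' @param lambda_grid Candidate sparsity values for per-block tuning.
#' @param folds Stratified cross-validation folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param screening_lambda Sparsity used during block selection
#'   (default 0.2).
#' @param tau Log-determinant barrier weight for the solver.
#' @param screen_top Optional: restrict attention to this many top-ranked
#'   features before blocking.
#' @return An object of class `sqda_fit` with elements `layout`, `model`
#'   (the fitted `cg_model`), `lambda_per_block`, `features` (original
#'   column indices used, in block order) and `config`. Methods:
#'   [predict.sqda_fit()], [tidy.sqda_fit()], [glance.sqda_fit()].
#' @examples
#' sim <- generate_data(sim_spec("ISSC", p = 60, n_train_per_class = 20,
#'                               n_test_per_class = 20, signal_count = 20,
#'                               seed = 7))
#' fit <- sqda(sim$train[-1], sim$train$class, block_size = 20)
#' mean(predict(fit, sim$test[-1]) != sim$test$class)
#' @export
sqda <- function(data, labels, block_size = 100L, error_margin = 0.05,
                 lambda_grid = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
                 folds = 5L, seed = 1L, screening_lambda = 0.2, tau = 1e-4,
                 screen_top = NULL) {
  .fit_block_pipeline(data, labels, estimator = "sparse",
                      block_size = block_size, error_margin = error_margin,
                      lambda_grid = sort(lambda_grid), folds = folds,
                      seed = seed, screening_lambda = screening_lambda,
                      tau = tau, screen_top = screen_top)
}

#' @rdname sqda
#' @export
dlda2 <- function(data, labels, block_size = 100L, error_margin = 0.05,
                  folds = 5L, seed = 1L, screen_top = NULL) {
  .fit_block_pipeline(data, labels, estimator = "diagonal-common",
                      block_size = block_size, error_margin = error_margin,
                      lambda_grid = NULL, folds = folds, seed = seed,
                      screening_lambda = 0.2, tau = 1e-4,
                      screen_top = screen_top)
}

#' @rdname sqda
#' @export
dqda2 <- function(data, labels, block_size = 100L, error_margin = 0.05,
                  folds = 5L, seed = 1L, screen_top = NULL) {
  .fit_block_pipeline(data, labels, estimator = "diagonal-perclass",
                      block_size = block_size, error_margin = error_margin,
                      lambda_grid = NULL, folds = folds, seed = seed,
                      screening_lambda = 0.2, tau = 1e-4,
                      screen_top = screen_top)
}

.fit_block_pipeline <- function(data, labels, estimator, block_size,
                                error_margin, lambda_grid, folds, seed,
                                screening_lambda, tau, screen_top) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  y <- droplevels(as.factor(labels))
  K <- nlevels(y)
  stat <- if (K == 2L) two_sample_t(x, y) else .anova_f(x, y)
  if (!is.null(screen_top)) {
    screen_top <- min(as.integer(screen_top), ncol(x))
    keep <- .rank_features(stat)[seq_len(screen_top)]  # already in rank order
    layout <- make_blocks(stat[keep], block_size)
    layout$feature_order <- keep[layout$feature_order]
    layout$blocks <- lapply(layout$blocks, function(b) keep[b])
  } else {
    layout <- make_blocks(stat, block_size)
  }
  layout <- select_blocks(x, y, layout, error_margin = error_margin,
                          folds = folds, seed = seed,
                          screening_lambda = screening_lambda,
                          estimator = estimator, tau = tau)
  sel <- which(layout$selected)
  fold_id <- .stratified_folds(y, folds, seed)

  lambda_per_block <- rep(NA_real_, layout$n_blocks)
  if (estimator == "sparse") {
    for (b in sel) {
      lambda_per_block[b] <- .tune_block_lambda(x, y, layout$blocks[[b]],
                                                fold_id, lambda_grid, tau)
    }
  }

  features <- unlist(layout$blocks[sel], use.names = FALSE)
  idx <- .class_split(y)
  means <- .class_means(x[, features, drop = FALSE], idx)
  block_cols <- split(seq_along(features), rep(seq_along(sel), each = layout$block_size))
  model <- switch(estimator,
    "sparse" = {
      covs <- lapply(idx, function(i) {
        lapply(seq_along(sel), function(j) {
          .sparse_block_cov(x[i, layout$blocks[[sel[j]]], drop = FALSE],
                            lam = lambda_per_block[sel[j]], tau = tau)
        })
      })
      new_cg_model(names(idx), means, unname(covs), kind = "blocks",
                   shared = FALSE, blocks = unname(block_cols))
    },
    "diagonal-common" = fit_dlda(x[, features, drop = FALSE], y),
    "diagonal-perclass" = fit_dqda(x[, features, drop = FALSE], y)
  )

  structure(
    list(layout = layout, model = model, lambda_per_block = lambda_per_block,
         features = features, feature_names = colnames(x)[features],
         estimator = estimator,
         config = list(block_size = layout$block_size,
                       error_margin = error_margin,
                       lambda_grid = lambda_grid, folds = folds, seed = seed,
                       screening_lambda = screening_lambda, tau = tau,
                       screen_top = screen_top)),
    class = "sqda_fit")
}

#' Predict from an SQDA fit
#'
#' Reindexes the test matrix through the fitted layout (original feature
#' columns retained at training time) and classifies by the
#' maximum-likelihood rule on the block-diagonal model.
#'
#' @param object An `sqda_fit`.
#' @param newdata Matrix or data frame containing at least the training
#'   features (matched by name when column names are present, by position
#'   otherwise).
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.sqda_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  nm <- object$feature_names
  if (!is.null(nm) && !is.null(colnames(x))) {
    missing <- setdiff(nm, colnames(x))
    if (length(missing) > 0L) {
      stop("test data is missing feature(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    x <- x[, nm, drop = FALSE]
  } else {
    if (ncol(x) < max(object$features)) {
      stop("test data has ", ncol(x), " columns but the model needs feature index ",
           max(object$features), ".", call. = FALSE)
    }
    x <- x[, object$features, drop = FALSE]
  }
  classify_ml(object$model, x)
}

#' @export
print.sqda_fit <- function(x, ...) {
  est <- c(sparse = "sparse block-diagonal QDA",
           `diagonal-common` = "block-selected diagonal LDA (DLDA2)",
           `diagonal-perclass` = "block-selected diagonal QDA (DQDA2)")[x$estimator]
  cat(est, "\n")
  cat(sprintf("  blocks: %d of %d selected (block size %d) -> %d features\n",
              sum(x$layout$selected), x$layout$n_blocks,
              x$layout$block_size, length(x$features)))
  if (x$estimator == "sparse") {
    cat(sprintf("  per-block lambda: %s\n",
                paste(x$lambda_per_block[x$layout$selected], collapse = ", ")))
  }
  invisible(x)
}

#' Tidy an SQDA fit
#'
#' @param x An `sqda_fit`.
#' @param ... Unused.
#' @return One row per block: its rank position, cross-validation error,
#'   selection status, and (for the sparse estimator) the tuned sparsity.
#' @export
tidy.sqda_fit <- function(x, ...) {
  tibble::tibble(
    block = seq_len(x$layout$n_blocks),
    n_features = lengths(x$layout$blocks),
    cv_error = x$layout$cv_error,
    selected = x$layout$selected,
    lambda = x$lambda_per_block
  )
}

#' @rdname tidy.sqda_fit
#' @export
glance.sqda_fit <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator,
    n_blocks = x$layout$n_blocks,
    n_selected = sum(x$layout$selected),
    n_features = length(x$features),
    block_size = x$layout$block_size,
    error_margin = x$config$error_margin,
    folds = x$config$folds,
    seed = x$config$seed
  )
}
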