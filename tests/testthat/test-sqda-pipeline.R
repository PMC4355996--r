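# small, well-separated two-class dataset used across the pipeline tests
make_toy <- function(p = 40, n = 30, shift = 1.5, signal = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n * p), 2 * n, p)
    x[seq_len(n), seq_len(signal)] <- x[seq_len(n), seq_len(signal)] + shift
  })
  colnames(x) <- paste0("g", seq_len(p))
  list(x = x, y = factor(rep(c("tumor", "normal"), each = n),
                         levels = c("tumor", "normal")))
}

test_that("two-sample t statistics match hand arithmetic", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  y <- rep(c("a", "b"), each = 3)
  # mean diff -3, pooled sd 1, se = sqrt(2/3)
  expect_equal(two_sample_t(x, y), -3 / sqrt(2 / 3), tolerance = 1e-12)

  # identical groups: t = 0
  x0 <- matrix(rep(c(1, 2, 3), 2), ncol = 1)
  expect_equal(two_sample_t(x0, y), 0)

  # and it agrees with t.test's pooled statistic on random data
  withr::with_seed(3, z <- matrix(rnorm(24), 12, 2))
  yz <- rep(c("a", "b"), each = 6)
  tt <- vapply(1:2, function(j) {
    unname(stats::t.test(z[1:6, j], z[7:12, j], var.equal = TRUE)$statistic)
  }, 0)
  expect_equal(two_sample_t(z, yz), tt, tolerance = 1e-10)

  # zero pooled variance is an error, as is a 1-sample class
  expect_error(two_sample_t(matrix(c(0, 0, 0, 1, 1, 1), ncol = 1), y),
               "pooled variance")
  expect_error(two_sample_t(matrix(rnorm(4), ncol = 1), c("a", "a", "a", "b")),
               "fewer than 2")
})

test_that("blocking sorts by |t|, drops remainders, and breaks ties by index", {
  t_stats <- c(0.1, -5, 2, 4.5, -0.2, 3, 1, -4, 0.5, 2.5)
  lay <- make_blocks(t_stats, 5)
  expect_equal(lay$n_blocks, 2L)
  expect_equal(lay$blocks[[1]], c(2L, 4L, 8L, 6L, 10L))  # top five by |t|
  expect_equal(length(unlist(lay$blocks)), 10L)

  lay3 <- make_blocks(t_stats, 3)
  expect_equal(lay3$n_blocks, 3L)
  expect_equal(length(lay3$feature_order), 9L)  # one feature dropped
  expect_equal(setdiff(seq_len(10), lay3$feature_order), 1L)  # the weakest

  # ties resolved towards the lower original index
  lay_tie <- make_blocks(c(2, -2, 2), 1)
  expect_equal(lay_tie$blocks[[1]], 1L)
  expect_equal(lay_tie$blocks[[2]], 2L)

  expect_error(make_blocks(t_stats, 11), "exceeds")
  expect_error(make_blocks(t_stats, 0), ">= 1")
})

test_that("block selection honours the error-margin contract", {
  toy <- make_toy(p = 40, n = 20, seed = 5)
  lay <- make_blocks(two_sample_t(toy$x, toy$y), 10)
  for (margin in c(0, 0.2, 0.5)) {
    sel <- select_blocks(toy$x, toy$y, lay, error_margin = margin,
                         seed = 2, estimator = "diagonal-common")
    expect_equal(sel$selected, sel$cv_error <= min(sel$cv_error) + margin)
    expect_true(any(sel$selected))          # the argmin block is always kept
    expect_true(sel$selected[which.min(sel$cv_error)])
  }
  # margin = 0 keeps exactly the minimum-error blocks
  sel0 <- select_blocks(toy$x, toy$y, lay, error_margin = 0, seed = 2,
                        estimator = "diagonal-common")
  expect_equal(which(sel0$selected), which(sel0$cv_error == min(sel0$cv_error)))

  expect_error(select_blocks(toy$x, toy$y, lay, error_margin = 0.7), "0, 0.5")
  expect_error(select_blocks(toy$x, toy$y, lay, folds = 25), "fewer samples")
})

test_that("a single-block fit reduces to sparse-covariance QDA on that block", {
  toy <- make_toy(p = 12, n = 25, signal = 12, seed = 8)
  fit <- sqda(toy$x, toy$y, block_size = 12, lambda_grid = 0.2, seed = 3)
  expect_equal(length(fit$features), 12L)
  expect_equal(fit$lambda_per_block, 0.2)

  # manual reconstruction: per class, penalized correlation at lam = 0.2
  # rescaled by class variances, then the ML rule
  idx <- split(seq_along(toy$y), toy$y)
  feats <- fit$features
  covs <- lapply(idx, function(i) {
    xb <- toy$x[i, feats, drop = FALSE]
    v <- apply(xb, 2, var)
    sol <- solve_penalized_correlation(sample_correlation(xb), lam = 0.2)
    correlation_to_covariance(sol, v)$sigma
  })
  means <- rbind(colMeans(toy$x[idx[[1]], feats]),
                 colMeans(toy$x[idx[[2]], feats]))
  manual <- sparseqda:::new_cg_model(names(idx), means, unname(covs),
                                    kind = "dense", shared = FALSE)
  te <- make_toy(p = 12, n = 15, signal = 12, seed = 9)
  expect_equal(predict(fit, te$x),
               classify_ml(manual, te$x[, feats]))
})

test_that("block-diagonal predictions equal a dense-covariance oracle", {
  toy <- make_toy(p = 30, n = 25, signal = 30, shift = 0.8, seed = 12)
  fit <- sqda(toy$x, toy$y, block_size = 10, error_margin = 0.5, seed = 6)
  expect_gt(sum(fit$layout$selected), 1)  # a genuinely block-diagonal model

  m <- fit$model
  p_model <- length(fit$features)
  te <- make_toy(p = 30, n = 10, signal = 30, shift = 0.8, seed = 13)
  xte <- te$x[, fit$features, drop = FALSE]
  scores <- vapply(seq_along(m$labels), function(k) {
    dense <- matrix(0, p_model, p_model)
    for (b in seq_along(m$blocks)) {
      dense[m$blocks[[b]], m$blocks[[b]]] <- m$covs[[k]][[b]]
    }
    dense_mvn_logdensity(xte, m$means[k, ], dense)
  }, numeric(nrow(xte)))
  oracle <- factor(m$labels[max.col(scores, ties.method = "first")],
                   levels = m$labels)
  expect_equal(predict(fit, te$x), oracle)
  # and the per-sample block log-densities match the dense oracle closely
  expect_equal(log_density(m, 1, xte), scores[, 1], tolerance = 1e-10)
})

test_that("a heavily penalized sparse fit matches the diagonal variant", {
  toy <- make_toy(p = 20, n = 30, signal = 20, shift = 2, seed = 21)
  fs <- sqda(toy$x, toy$y, block_size = 10, error_margin = 0.5,
             lambda_grid = 50, screening_lambda = 50, seed = 4)
  fd <- dqda2(toy$x, toy$y, block_size = 10, error_margin = 0.5, seed = 4)
  expect_equal(fs$features, fd$features)  # same layout and selection path
  te <- make_toy(p = 20, n = 20, signal = 20, shift = 2, seed = 22)
  expect_equal(predict(fs, te$x), predict(fd, te$x))
})

test_that("fits are deterministic and predictions are order-invariant", {
  toy <- make_toy(seed = 31)
  f1 <- sqda(toy$x, toy$y, block_size = 10, seed = 7)
  f2 <- sqda(toy$x, toy$y, block_size = 10, seed = 7)
  expect_equal(f1$layout$cv_error, f2$layout$cv_error)
  expect_equal(f1$lambda_per_block, f2$lambda_per_block)
  te <- make_toy(n = 17, seed = 32)
  expect_equal(predict(f1, te$x), predict(f2, te$x))

  perm <- sample(nrow(te$x))
  expect_equal(predict(f1, te$x[perm, ]), predict(f1, te$x)[perm])

  # missing features in the test matrix are an error
  expect_error(predict(f1, te$x[, 1:5]), "missing feature")
})

test_that("DLDA2/DQDA2 share the selection path and tidy/glance are coherent", {
  toy <- make_toy(seed = 41)
  f_l <- dlda2(toy$x, toy$y, block_size = 10, seed = 9)
  f_q <- dqda2(toy$x, toy$y, block_size = 10, seed = 9)
  # identical layout (ranking does not depend on the estimator)
  expect_equal(f_l$layout$blocks, f_q$layout$blocks)
  expect_true(all(is.na(f_l$lambda_per_block)))

  td <- tidy(f_l)
  expect_equal(nrow(td), f_l$layout$n_blocks)
  expect_equal(sum(td$selected), glance(f_l)$n_selected)
  expect_equal(glance(f_l)$n_features, length(f_l$features))
})

test_that("fitted models survive a JSON round trip", {
  toy <- make_toy(p = 20, n = 20, seed = 51)
  te <- make_toy(p = 20, n = 10, seed = 52)
  for (fitter in list(sqda, dlda2, dqda2)) {
    fit <- fitter(toy$x, toy$y, block_size = 10, seed = 2)
    path <- withr::local_tempfile(fileext = ".json")
    write_sqda_model(fit, path)
    back <- read_sqda_model(path)
    expect_equal(predict(back, te$x), predict(fit, te$x))
    expect_equal(back$layout$cv_error, fit$layout$cv_error, tolerance = 1e-12)
  }
})

test_that("per-class estimates recover the rewired sign pattern", {
  # DSDC-style data: class 2 flips the AR sign of the first two 200-feature
  # blocks, so for originally adjacent feature pairs in that region the two
  # classes' fitted covariance entries should disagree in sign
  spec <- sim_spec("DSDC", p = 600, n_train_per_class = 50,
                   n_test_per_class = 10, signal_count = 400, ar_block = 200,
                   seed = 71)
  d <- generate_data(spec)
  fit <- suppressWarnings(sqda(d$train[-1], d$train$class, seed = 72))
  m <- fit$model
  agree <- c()
  for (b in seq_along(m$blocks)) {
    feats <- fit$features[m$blocks[[b]]]  # original indices of this block
    s1 <- m$covs[[1]][[b]]; s2 <- m$covs[[2]][[b]]
    for (i in seq_along(feats)) for (j in seq_len(i - 1L)) {
      # adjacent original pairs inside the rewired region
      if (abs(feats[i] - feats[j]) == 1L && max(feats[i], feats[j]) <= 400L &&
          s1[i, j] != 0 && s2[i, j] != 0) {
        agree <- c(agree, sign(s1[i, j]) != sign(s2[i, j]))
      }
    }
  }
  expect_gt(length(agree), 20)   # plenty of adjacent rewired pairs survive
  expect_gt(mean(agree), 0.6)    # and they mostly disagree in sign
})

test_that("the optional top-feature screen restricts the layout", {
  toy <- make_toy(p = 40, n = 20, seed = 61)
  fit <- dlda2(toy$x, toy$y, block_size = 10, screen_top = 20, seed = 2)
  expect_equal(fit$layout$n_blocks, 2L)
  top20 <- order(-abs(two_sample_t(toy$x, toy$y)), seq_len(40))[1:20]
  expect_true(all(unlist(fit$layout$blocks) %in% top20))
})
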