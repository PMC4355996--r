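# Method registry: each entry fits on the training set (tuning included),
# predicts the test set, and reports the misclassification rate plus the
# number of features the tuned rule uses (NA when the method has no
# feature-selection notion). `control` carries the pipeline settings.
.bench_methods <- function() {
  screen_then <- function(rule) {
    function(xtr, ytr, xte, yte, seed, control) {
      scr <- top_gene_cv_screen(xtr, ytr, method = rule,
                                counts = control$counts,
                                folds = control$folds, seed = seed,
                                h = control$h)
      stat <- if (nlevels(ytr) == 2L) two_sample_t(xtr, ytr) else .anova_f(xtr, ytr)
      feat <- .rank_features(stat)[seq_len(scr$count)]
      pred <- .fit_predict_rule(rule, xtr[, feat, drop = FALSE], ytr,
                                xte[, feat, drop = FALSE], control$h)
      list(error = mean(pred != yte), n_features = scr$count)
    }
  }
  block_method <- function(fitter, sparse) {
    function(xtr, ytr, xte, yte, seed, control) {
      args <- list(xtr, ytr, block_size = control$block_size,
                   error_margin = control$error_margin,
                   folds = control$folds, seed = seed,
                   screen_top = control$screen_top)
      if (sparse) {
        args$lambda_grid <- control$lambda_grid
        args$screening_lambda <- control$screening_lambda
      }
      fit <- do.call(fitter, args)
      list(error = mean(predict(fit, xte) != yte),
           n_features = length(fit$features))
    }
  }
  list(
    dlda = screen_then("dlda"),
    dqda = screen_then("dqda"),
    nn = screen_then("nn"),
    scrda = function(xtr, ytr, xte, yte, seed, control) {
      fit <- scrda(xtr, ytr, folds = control$folds, seed = seed)
      list(error = mean(predict(fit, xte) != yte),
           n_features = fit$n_features)
    },
    sqda = block_method(sqda, sparse = TRUE),
    dlda2 = block_method(dlda2, sparse = FALSE),
    dqda2 = block_method(dqda2, sparse = FALSE),
    svm = function(xtr, ytr, xte, yte, seed, control) {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("package 'e1071' is not installed; cannot run svm.", call. = FALSE)
      }
      scr_stat <- if (nlevels(ytr) == 2L) two_sample_t(xtr, ytr) else .anova_f(xtr, ytr)
      best <- .svm_screen(xtr, ytr, control, seed)
      feat <- .rank_features(scr_stat)[seq_len(best)]
      fit <- e1071::svm(xtr[, feat, drop = FALSE], ytr, kernel = "linear")
      pred <- predict(fit, xte[, feat, drop = FALSE])
      list(error = mean(pred != yte), n_features = best)
    },
    rf = function(xtr, ytr, xte, yte, seed, control) {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("package 'randomForest' is not installed; cannot run rf.", call. = FALSE)
      }
      fit <- withr::with_seed(seed, randomForest::randomForest(xtr, ytr))
      pred <- predict(fit, xte)
      list(error = mean(pred != yte), n_features = NA_integer_)
    }
  )
}

.svm_screen <- function(xtr, ytr, control, seed) {
  fold_id <- .stratified_folds(ytr, control$folds, seed)
  counts <- control$counts[control$counts <= ncol(xtr)]
  stat <- if (nlevels(ytr) == 2L) two_sample_t(xtr, ytr) else .anova_f(xtr, ytr)
  ord <- .rank_features(stat)
  wrong <- numeric(length(counts))
  for (f in seq_len(max(fold_id))) {
    tr <- fold_id != f
    for (j in seq_along(counts)) {
      feat <- ord[seq_len(counts[j])]
      fit <- e1071::svm(xtr[tr, feat, drop = FALSE], ytr[tr], kernel = "linear")
      pred <- predict(fit, xtr[!tr, feat, drop = FALSE])
      wrong[j] <- wrong[j] + sum(pred != ytr[!tr])
    }
  }
  counts[which.min(wrong)]
}

#' Default benchmarking control settings
#'
#' @param block_size,error_margin,lambda_grid,screening_lambda,screen_top
#'   Settings forwarded to [sqda()] and its diagonal variants.
#' @param counts Candidate top-gene counts for the screened rules.
#' @param folds Cross-validation folds used everywhere.
#' @param h Neighbours for the nearest-neighbour rule.
#' @return A named list.
#' @export
benchmark_control <- function(block_size = 100L, error_margin = 0.05,
                              lambda_grid = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
                              screening_lambda = 0.2,
                              counts = seq(50L, 2000L, by = 50L),
                              folds = 5L, h = 3L, screen_top = NULL) {
  list(block_size = block_size, error_margin = error_margin,
       lambda_grid = lambda_grid, screening_lambda = screening_lambda,
       counts = counts, folds = folds, h = h, screen_top = screen_top)
}

#' Aggregate replicate errors into a benchmark summary
#'
#' Pure aggregation of a per-replicate result table: mean and standard
#' deviation (n - 1 denominator) of the error over replicates, and the
#' median number of selected features. With a single replicate the standard
#' deviation is reported as 0 and flagged via `sd_defined = FALSE`.
#'
#' @param results Tibble with columns `method`, `replicate`, `error`,
#'   `n_features`.
#' @return One row per method: `mean_error`, `sd_error`, `sd_defined`,
#'   `median_features`, `n_replicates`.
#' @export
aggregate_benchmark <- function(results) {
  results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_error = mean(.data$error),
      sd_error = if (dplyr::n() > 1L) stats::sd(.data$error) else 0,
      sd_defined = dplyr::n() > 1L,
      median_features = if (all(is.na(.data$n_features))) NA_real_
                        else stats::median(.data$n_features, na.rm = TRUE),
      n_replicates = dplyr::n(),
      .groups = "drop")
}

#' Run a multi-replicate simulation benchmark
#'
#' Generates `replicates` independent datasets from `spec` (with seeds
#' derived deterministically from `seed`), runs every requested method on
#' identical data within each replicate, and aggregates test
#' misclassification rates. A method failing on a replicate is recorded,
#' excluded from aggregation, and reported via a message.
#'
#' @param spec A [sim_spec()]; its `seed` field is overridden per
#'   replicate.
#' @param methods Character vector among `"dlda"`, `"dqda"`, `"nn"`,
#'   `"scrda"`, `"sqda"`, `"dlda2"`, `"dqda2"`, `"svm"`, `"rf"`.
#' @param replicates Number of independent datasets.
#' @param seed Master seed from which replicate and method seeds derive.
#' @param control Settings from [benchmark_control()].
#' @return An object of class `benchmark_result`: list with `summary`
#'   (the [aggregate_benchmark()] tibble plus a `setting` column) and
#'   `replicates` (the per-replicate table).
#' @export
benchmark_setting <- function(spec, methods = c("dlda", "dqda", "nn", "scrda",
                                                "sqda", "dlda2", "dqda2"),
                              replicates = 10L, seed = 1L,
                              control = benchmark_control()) {
  stopifnot(inherits(spec, "sim_spec"), replicates >= 1L)
  registry <- .bench_methods()
  bad <- setdiff(methods, names(registry))
  if (length(bad) > 0L) stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, replicates))
  rows <- list()
  failures <- 0L
  for (i in seq_len(replicates)) {
    spec_i <- spec
    spec_i$seed <- rep_seeds[i]
    d <- generate_data(spec_i)
    xtr <- as.matrix(d$train[-1L]); ytr <- d$train$class
    xte <- as.matrix(d$test[-1L]); yte <- d$test$class
    for (j in seq_along(methods)) {
      # the seed is intrinsic to the method (registry position), so a method
      # sees the same folds whether it is run alone or alongside others
      method_seed <- (rep_seeds[i] +
                        7919L * match(methods[j], names(registry))) %% .Machine$integer.max
      res <- tryCatch(
        registry[[methods[j]]](xtr, ytr, xte, yte, method_seed, control),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- failures + 1L
        message("method '", methods[j], "' failed on replicate ", i, ": ",
                conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = methods[j], replicate = i, error = res$error,
        n_features = as.numeric(res$n_features))
    }
  }
  detail <- dplyr::bind_rows(rows)
  summary <- aggregate_benchmark(detail) |>
    dplyr::mutate(setting = spec$setting, .before = 1L)
  structure(list(summary = summary, replicates = detail, spec = spec,
                 n_failed = failures, control = control),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: %s, %d replicate(s)\n", x$spec$setting,
              max(x$replicates$replicate)))
  print(x$summary)
  if (x$n_failed > 0L) cat(x$n_failed, "method-replicate failure(s) excluded\n")
  invisible(x)
}

#' @export
tidy.benchmark_result <- function(x, ...) x$summary

#' Plot a benchmark summary
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot: mean misclassification rate per method with one
#'   standard deviation error bars.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = stats::reorder(.data$method, .data$mean_error),
                                  y = .data$mean_error)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$mean_error - .data$sd_error),
                                        ymax = .data$mean_error + .data$sd_error),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean test misclassification rate",
                  title = paste0(object$spec$setting, " benchmark")) +
    ggplot2::theme_minimal()
}

#' Sweep one tuning parameter of the benchmark
#'
#' Re-runs [benchmark_setting()] for a single method across a grid of one
#' parameter: the block size, the error margin, or the per-class training
#' sample size.
#'
#' @param spec A [sim_spec()].
#' @param parameter One of `"block_size"`, `"error_margin"`,
#'   `"n_train_per_class"`.
#' @param values Grid of parameter values.
#' @param method A single method name.
#' @param replicates Replicates per grid value.
#' @param seed Master seed (shared across grid values, so each value sees
#'   the same datasets unless the parameter itself changes the generator).
#' @param control Settings from [benchmark_control()].
#' @return An object of class `benchmark_sweep`: a long tibble with columns
#'   `parameter`, `value` and the summary columns.
#' @export
benchmark_sweep <- function(spec, parameter = c("block_size", "error_margin",
                                                "n_train_per_class"),
                            values, method = "sqda", replicates = 5L,
                            seed = 1L, control = benchmark_control()) {
  parameter <- match.arg(parameter)
  stopifnot(length(method) == 1L)
  rows <- purrr::map(values, function(v) {
    spec_v <- spec
    ctrl_v <- control
    if (parameter == "n_train_per_class") spec_v$n_train_per_class <- as.integer(v)
    else ctrl_v[[parameter]] <- v
    res <- benchmark_setting(spec_v, methods = method,
                             replicates = replicates, seed = seed,
                             control = ctrl_v)
    dplyr::mutate(res$summary, parameter = parameter, value = v, .before = 1L)
  })
  structure(dplyr::bind_rows(rows), class = c("benchmark_sweep", "tbl_df",
                                              "tbl", "data.frame"))
}

#' Plot a parameter sweep
#'
#' @param object A `benchmark_sweep`.
#' @param ... Unused.
#' @return A ggplot of mean error against the swept parameter value.
#' @export
autoplot.benchmark_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$mean_error)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$mean_error - .data$sd_error),
                                        ymax = .data$mean_error + .data$sd_error),
                           width = 0) +
    ggplot2::labs(x = unique(object$parameter), y = "mean test misclassification rate") +
    ggplot2::theme_minimal()
}
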