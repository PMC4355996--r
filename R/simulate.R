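#' Autoregressive correlation block
#'
#' Builds the `dim x dim` AR(1)-type correlation matrix with entry
#' `rho^|i - j|`: a symmetric Toeplitz matrix with unit diagonal, positive
#' definite for any `|rho| < 1`. Negative `rho` alternates the sign of the
#' correlations with lag.
#'
#' @param dim Block dimension.
#' @param rho Autoregressive parameter, `|rho| < 1`.
#' @return A `dim x dim` correlation matrix.
#' @examples
#' ar_cor(3, 0.95)
#' @export
ar_cor <- function(dim, rho) {
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1.", call. = FALSE)
  idx <- seq_len(dim)
  rho^abs(outer(idx, idx, "-"))
}

#' Simulation specification
#'
#' Describes one of the four benchmark covariance regimes for two-class
#' "tumor" vs "normal" expression data:
#'
#' * `ISSC` (independent structure, same covariance): both classes have
#'   identity covariance.
#' * `ISDC` (independent, different): class 1's first `signal_count`
#'   variances are raised to `var_shift`.
#' * `DSSC` (dependent, same): both classes share a block-diagonal
#'   covariance whose `ar_block`-dimensional blocks alternate between
#'   AR(`rho`) and AR(`-rho`) correlation, from the top down.
#' * `DSDC` (dependent, different): as DSSC, but class 2 has the sign order
#'   of the first two blocks reversed.
#'
#' In every regime class 1 ("tumor") has mean `mean_shift` in its first
#' `signal_count` coordinates and 0 elsewhere; class 2 ("normal") has mean
#' zero.
#'
#' @param setting One of `"ISSC"`, `"ISDC"`, `"DSSC"`, `"DSDC"`.
#' @param p Number of features (default 10,000).
#' @param n_train_per_class,n_test_per_class Samples per class in the
#'   training and test sets (defaults 50 and 500).
#' @param signal_count Number of mean-shifted features (default 400).
#' @param mean_shift Mean of class 1 on the signal features (default 0.5).
#' @param var_shift Class-1 variance of the signal features under ISDC
#'   (default 1.5).
#' @param rho AR parameter of the dependent regimes (default 0.95).
#' @param ar_block AR block dimension (default 200); must divide `p` for
#'   the dependent regimes.
#' @param seed Integer seed making [generate_data()] reproducible.
#' @param scale Optional proportional down-scaling factor applied to `p`,
#'   the sample sizes, `signal_count` and `ar_block` (e.g. `scale = 0.1`
#'   turns the default into p = 1000 with 40 signal features and AR blocks
#'   of 20). Useful for quick runs; note that proportional scaling shrinks
#'   the class separation, so error rates are not comparable with the
#'   full-size regime.
#' @return An object of class `sim_spec` (a list of the above fields).
#' @export
sim_spec <- function(setting = c("ISSC", "ISDC", "DSSC", "DSDC"),
                     p = 10000L, n_train_per_class = 50L,
                     n_test_per_class = 500L, signal_count = 400L,
                     mean_shift = 0.5, var_shift = 1.5, rho = 0.95,
                     ar_block = 200L, seed = 1L, scale = 1) {
  setting <- match.arg(setting)
  if (scale != 1) {
    rescale <- function(v) max(1L, as.integer(round(v * scale)))
    p <- rescale(p); n_train_per_class <- rescale(n_train_per_class)
    n_test_per_class <- rescale(n_test_per_class)
    signal_count <- rescale(signal_count); ar_block <- rescale(ar_block)
  }
  if (signal_count > p) stop("`signal_count` must be <= p.", call. = FALSE)
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1.", call. = FALSE)
  if (setting %in% c("DSSC", "DSDC") && p %% ar_block != 0) {
    stop("`ar_block` must divide `p` for the dependent regimes.", call. = FALSE)
  }
  structure(
    list(setting = setting, p = as.integer(p),
         n_train_per_class = as.integer(n_train_per_class),
         n_test_per_class = as.integer(n_test_per_class),
         signal_count = as.integer(signal_count), mean_shift = mean_shift,
         var_shift = var_shift, rho = rho, ar_block = as.integer(ar_block),
         seed = as.integer(seed)),
    class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("Simulation spec: %s, p = %d, %d + %d train, %d + %d test\n",
              x$setting, x$p, x$n_train_per_class, x$n_train_per_class,
              x$n_test_per_class, x$n_test_per_class))
  cat(sprintf("  signal: first %d features, mean shift %g; rho = %g, AR block %d; seed %d\n",
              x$signal_count, x$mean_shift, x$rho, x$ar_block, x$seed))
  invisible(x)
}

#' Class covariance under a simulation spec
#'
#' Returns the covariance of one class in block form. For the independent
#' regimes the result is `list(kind = "diagonal", variances = ...)`; for the
#' dependent regimes `list(kind = "ar", signs = ...)` where `signs` gives
#' the sign of `rho` for each `ar_block`-dimensional AR block, plus the two
#' distinct block matrices in `blocks`.
#'
#' @param spec A [sim_spec()].
#' @param class_index 1 (tumor) or 2 (normal).
#' @return A list describing the block-diagonal covariance.
#' @export
sim_covariance <- function(spec, class_index) {
  stopifnot(inherits(spec, "sim_spec"), class_index %in% c(1L, 2L))
  if (spec$setting %in% c("ISSC", "ISDC")) {
    v <- rep(1, spec$p)
    if (spec$setting == "ISDC" && class_index == 1L) {
      v[seq_len(spec$signal_count)] <- spec$var_shift
    }
    return(list(kind = "diagonal", variances = v))
  }
  n_blocks <- spec$p %/% spec$ar_block
  signs <- rep_len(c(1, -1), n_blocks)  # alternation continues down the diagonal
  if (spec$setting == "DSDC" && class_index == 2L && n_blocks >= 2L) {
    signs[1:2] <- signs[2:1]
  }
  list(kind = "ar", signs = signs,
       blocks = list(pos = ar_cor(spec$ar_block, spec$rho),
                     neg = ar_cor(spec$ar_block, -spec$rho)))
}

# draw n multivariate normal rows for one class, block by block
.draw_class <- function(n, spec, class_index, chol_cache) {
  cv <- sim_covariance(spec, class_index)
  if (cv$kind == "diagonal") {
    x <- matrix(stats::rnorm(n * spec$p), n, spec$p)
    x <- sweep(x, 2L, sqrt(cv$variances), "*")
  } else {
    x <- matrix(0, n, spec$p)
    for (b in seq_along(cv$signs)) {
      cols <- ((b - 1L) * spec$ar_block + 1L):(b * spec$ar_block)
      u <- if (cv$signs[b] > 0) chol_cache$pos else chol_cache$neg
      x[, cols] <- matrix(stats::rnorm(n * spec$ar_block), n, spec$ar_block) %*% u
    }
  }
  if (class_index == 1L) {
    x[, seq_len(spec$signal_count)] <-
      x[, seq_len(spec$signal_count)] + spec$mean_shift
  }
  x
}

#' Generate a simulated two-class expression dataset
#'
#' Draws the training and test sets described by a [sim_spec()]: class 1
#' ("tumor") from `N(mu_1, Sigma_1)` and class 2 ("normal") from
#' `N(mu_2, Sigma_2)`, sampling block by block (valid because every
#' regime's covariance is block-diagonal). The same seed always reproduces
#' the same data.
#'
#' @param spec A [sim_spec()].
#' @return A list with tibbles `train` and `test`; each has a `class`
#'   factor column (levels `tumor`, `normal`) followed by feature columns
#'   `g1 ... gp`.
#' @examples
#' d <- generate_data(sim_spec("ISSC", p = 20, n_train_per_class = 5,
#'                             n_test_per_class = 5, signal_count = 10))
#' dim(d$train)
#' @export
generate_data <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  chol_cache <- NULL
  if (spec$setting %in% c("DSSC", "DSDC")) {
    chol_cache <- list(pos = chol(ar_cor(spec$ar_block, spec$rho)),
                       neg = chol(ar_cor(spec$ar_block, -spec$rho)))
  }
  build <- function(n_per_class) {
    x <- rbind(.draw_class(n_per_class, spec, 1L, chol_cache),
               .draw_class(n_per_class, spec, 2L, chol_cache))
    colnames(x) <- paste0("g", seq_len(spec$p))
    out <- tibble::as_tibble(x)
    out <- dplyr::bind_cols(
      tibble::tibble(class = factor(rep(c("tumor", "normal"), each = n_per_class),
                                    levels = c("tumor", "normal"))),
      out)
    out
  }
  withr::with_seed(spec$seed, {
    train <- build(spec$n_train_per_class)
    test <- build(spec$n_test_per_class)
  })
  list(train = train, test = test, spec = spec)
}
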