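#' Save and restore fitted models as JSON
#'
#' Serializes an [sqda()] (or `dlda2()`/`dqda2()`) fit — layout, class
#' means, covariance blocks and configuration — to a self-contained JSON
#' document, so a model can be fitted once and used for prediction in a
#' later session or from the command line.
#'
#' @param fit An `sqda_fit`.
#' @param path File to write.
#' @return `write_sqda_model()` returns `path` invisibly;
#'   `read_sqda_model()` returns the restored `sqda_fit`.
#' @export
write_sqda_model <- function(fit, path) {
  stopifnot(inherits(fit, "sqda_fit"))
  m <- fit$model
  covs <- if (m$shared) list(m$covs[[1L]]) else m$covs
  doc <- list(
    package = "sparseqda", format = 1L,
    estimator = fit$estimator,
    labels = m$labels,
    means = m$means,
    kind = m$kind,
    shared = m$shared,
    covs = covs,
    blocks = m$blocks,
    features = fit$features,
    feature_names = fit$feature_names,
    lambda_per_block = fit$lambda_per_block,
    layout = list(feature_order = fit$layout$feature_order,
                  block_size = fit$layout$block_size,
                  n_blocks = fit$layout$n_blocks,
                  blocks = fit$layout$blocks,
                  selected = fit$layout$selected,
                  cv_error = fit$layout$cv_error),
    config = fit$config
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_sqda_model
#' @export
read_sqda_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$package, "sparseqda")) {
    stop("not a sparseqda model file.", call. = FALSE)
  }
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r) unlist(r, use.names = FALSE)))
  as_num <- function(v) {  # JSON nulls inside arrays come back as NULL elements
    if (!is.list(v)) return(v)
    unlist(lapply(v, function(e) if (is.null(e)) NA else e), use.names = FALSE)
  }
  kind <- doc$kind
  covs <- switch(kind,
    "blocks" = lapply(doc$covs, function(cl) lapply(cl, as_mat)),
    "dense" = lapply(doc$covs, as_mat),
    "diagonal" = lapply(doc$covs, as_num))
  blocks <- if (is.null(doc$blocks)) NULL else lapply(doc$blocks, function(b) as.integer(as_num(b)))
  model <- new_cg_model(as_num(doc$labels), as_mat(doc$means), covs, kind,
                        isTRUE(doc$shared), blocks = blocks)
  layout <- structure(
    list(feature_order = as.integer(as_num(doc$layout$feature_order)),
         block_size = as.integer(doc$layout$block_size),
         n_blocks = as.integer(doc$layout$n_blocks),
         blocks = lapply(doc$layout$blocks, function(b) as.integer(as_num(b))),
         selected = as.logical(as_num(doc$layout$selected)),
         cv_error = as.numeric(as_num(doc$layout$cv_error))),
    class = "block_layout")
  structure(
    list(layout = layout, model = model,
         lambda_per_block = as.numeric(as_num(doc$lambda_per_block)),
         features = as.integer(as_num(doc$features)),
         feature_names = if (is.null(doc$feature_names)) NULL else as_num(doc$feature_names),
         estimator = doc$estimator,
         config = lapply(doc$config, function(v) if (length(v)) as_num(v) else NULL)),
    class = "sqda_fit")
}
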