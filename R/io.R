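# Plain-text (JSON) serialization of the data containers: epoch sets,
# covariance sets, fitted means fields, and prediction tables. Matrices are
# stored as row-major flattened vectors with explicit dimensions plus a
# metadata block, one self-describing file per object.

mat_to_list <- function(M) list(dim = dim(M), values = as.vector(t(M)))

list_to_mat <- function(l) {
  matrix(l$values, nrow = l$dim[1], ncol = l$dim[2], byrow = TRUE)
}

#' Write / read a covariance set as JSON
#'
#' @param set a [cov_set()].
#' @param path file path.
#' @return `read_cov_set` returns a [cov_set()]; `write_cov_set` its path,
#'   invisibly.
#' @export
write_cov_set <- function(set, path) {
  check_set(set)
  obj <- list(container = "cov_set", dim = set$dim,
              covs = lapply(set$matrices, function(m) as.vector(t(m))),
              labels = if (!is.null(set$labels)) as.character(set$labels),
              weights = set$weights)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cov_set
#' @export
read_cov_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$container, "cov_set")) stop("not a cov_set container")
  n <- obj$dim
  mats <- lapply(obj$covs, function(v)
    matrix(unlist(v), n, n, byrow = TRUE))
  cov_set(mats, labels = if (!is.null(obj$labels)) unlist(obj$labels),
          weights = unlist(obj$weights))
}

#' Write / read an epoch set as JSON
#'
#' @param epochs an `epoch_set`.
#' @param path file path.
#' @return `read_epoch_set` returns an `epoch_set`; `write_epoch_set` its
#'   path, invisibly.
#' @export
write_epoch_set <- function(epochs, path) {
  if (!inherits(epochs, "epoch_set")) stop("expected an epoch_set")
  obj <- list(container = "epoch_set", n_channels = epochs$n_channels,
              n_samples = epochs$n_samples,
              epochs = lapply(epochs$epochs, function(m) as.vector(t(m))),
              labels = as.character(epochs$labels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$container, "epoch_set"))
    stop("not an epoch_set container")
  eps <- lapply(obj$epochs, function(v)
    matrix(unlist(v), obj$n_channels, obj$n_samples, byrow = TRUE))
  structure(list(epochs = eps, labels = factor(unlist(obj$labels)),
                 n_channels = obj$n_channels, n_samples = obj$n_samples),
            class = "epoch_set")
}

#' Write / read a fitted means field as JSON
#'
#' Stores the per-class means (class-major, h ascending), the exponent
#' field, and the iteration diagnostics.
#'
#' @param field a `means_field`.
#' @param path file path.
#' @return `read_means_field` returns a `means_field`; `write_means_field`
#'   its path, invisibly.
#' @export
write_means_field <- function(field, path) {
  if (!inherits(field, "means_field")) stop("expected a means_field")
  obj <- list(container = "means_field", dim = field$dim,
              classes = field$classes, h_values = field$h_values,
              means = stats::setNames(
                lapply(field$classes, function(cl)
                  lapply(field$means[[cl]], function(m) as.vector(t(m)))),
                field$classes),
              diagnostics = field$diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_means_field
#' @export
read_means_field <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$container, "means_field"))
    stop("not a means_field container")
  n <- obj$dim
  means <- lapply(obj$means, function(cl)
    lapply(cl, function(v) matrix(unlist(v), n, n, byrow = TRUE)))
  diagnostics <- if (!is.null(obj$diagnostics))
    do.call(rbind, lapply(obj$diagnostics, function(r)
      data.frame(h = r$h, iterations = r$iterations,
                 residual = r$residual, class = r$class)))
  structure(list(means = means, classes = unlist(obj$classes),
                 h_values = unlist(obj$h_values), dim = n,
                 diagnostics = diagnostics),
            class = "means_field")
}

#' Write predictions as CSV
#'
#' One row per trial: trial id, predicted class, continuous score.
#'
#' @param pred prediction data frame from a `predict` method.
#' @param path file path.
#' @export
write_predictions <- function(pred, path) {
  out <- data.frame(trial = seq_len(nrow(pred)), class = pred$class,
                    score = pred$score)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
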