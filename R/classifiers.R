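# Manifold classifiers over trial covariance matrices.
#
# mdm():  minimum distance to the per-class geometric mean.
# mdmf(): minimum distance over the whole field of power means.
# mf():   squared affine-invariant distances to every mean in the field,
#         fed to a closed-form linear discriminant.
#
# All three are deterministic: fitting and prediction involve no randomness,
# so repeated runs on identical input agree bitwise. Binary scores are
# oriented so that larger values indicate the second class level; exact ties
# are broken toward the lower-indexed class.

resolve_field <- function(set, h_values, tol, maxit, robust, z_threshold,
                          max_refinements, min_retained) {
  if (robust) {
    robust_means_field(set, h_values, tol, maxit, z_threshold,
                       max_refinements, min_retained)
  } else {
    compute_means_field(set, h_values, tol, maxit)
  }
}

#' Minimum-distance-to-mean (MDM) classifier
#'
#' Learns the geometric mean of each class; an unlabeled trial is assigned
#' to the class of the nearest mean under the affine-invariant metric.
#'
#' @param set labeled [cov_set()] with at least 2 classes.
#' @param tol,maxit geometric-mean solver controls.
#' @param robust screen outliers per class with [robust_mean()] before
#'   estimating the means.
#' @param z_threshold,max_refinements,min_retained robust-screen controls.
#' @return object of class `mdm` (a fitted means field restricted to h = 0).
#' @seealso [mdmf()], [mf()]
#' @export
mdm <- function(set, tol = 1e-7, maxit = 150L, robust = FALSE,
                z_threshold = 2.5, max_refinements = 4L, min_retained = 2L) {
  check_set(set)
  if (is.null(set$labels) || nlevels(set$labels) < 2L)
    stop("labeled set with at least 2 classes required")
  field <- resolve_field(set, h_values = 0, tol, maxit, robust,
                         z_threshold, max_refinements, min_retained)
  structure(list(field = field, classes = field$classes), class = "mdm")
}

#' Minimum-distance-to-means-field (MDMF) classifier
#'
#' Learns the full field of power means per class; an unlabeled trial is
#' assigned to the class owning the globally nearest mean among all
#' (class, h) means.
#'
#' @inheritParams mdm
#' @param h_values power-mean exponents (default [default_h_field()]).
#' @return object of class `mdmf`.
#' @export
mdmf <- function(set, h_values = default_h_field(), tol = 1e-7,
                 maxit = 150L, robust = FALSE, z_threshold = 2.5,
                 max_refinements = 4L, min_retained = 2L) {
  check_set(set)
  if (is.null(set$labels) || nlevels(set$labels) < 2L)
    stop("labeled set with at least 2 classes required")
  field <- resolve_field(set, h_values, tol, maxit, robust,
                         z_threshold, max_refinements, min_retained)
  structure(list(field = field, classes = field$classes), class = "mdmf")
}

# squared distances from one SPD matrix to every mean of one class, h
# ascending
class_sqdists <- function(field, cls, C) {
  ms <- field$means[[cls]]
  vapply(h_key(field$h_values), function(k) airm_distance(C, ms[[k]])^2,
         numeric(1))
}

#' Squared-distance feature vector for the MF classifier
#'
#' Squared affine-invariant distances from a trial to every mean in the
#' field, ordered class-major then h ascending; length =
#' (number of classes) x (number of h values).
#'
#' @param field a `means_field`.
#' @param C SPD matrix (one trial covariance).
#' @return numeric feature vector.
#' @export
mf_features <- function(field, C) {
  if (!all(dim(C) == c(field$dim, field$dim))) stop("dimension mismatch")
  unlist(lapply(field$classes, class_sqdists, field = field, C = C),
         use.names = FALSE)
}

# ---- Linear discriminant (closed form) -----------------------------------

#' Fit a closed-form linear discriminant
#'
#' Pooled within-class covariance (divisor N - number of classes) with a
#' ridge of `1e-6 * tr(S)/p` added when the pooled matrix is singular;
#' direction \eqn{\Sigma_w^{-1} (\mu_1 - \mu_0)}; intercept from the class
#' means and the empirical class priors. The decision score is the signed
#' linear function, positive toward the second class level. No tuned
#' hyperparameters. For more than two classes a one-versus-rest set of
#' binary discriminants is fitted and prediction takes the argmax score.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y class labels (factor or coercible), at least 2 per class.
#' @return object of class `lda_discriminant` with elements `w`
#'   (direction), `b` (intercept) for the binary case, or `ovr` (list of
#'   binary fits) otherwise.
#' @export
lda_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  if (any(table(y) < 2L)) stop("each class needs at least 2 samples")
  lv <- levels(y)
  if (length(lv) > 2L) {
    ovr <- lapply(lv, function(l) lda_fit(x, factor(y == l, c(FALSE, TRUE))))
    return(structure(list(ovr = ovr, classes = lv),
                     class = "lda_discriminant"))
  }
  p <- ncol(x)
  mu0 <- colMeans(x[y == lv[1], , drop = FALSE])
  mu1 <- colMeans(x[y == lv[2], , drop = FALSE])
  n0 <- sum(y == lv[1]); n1 <- sum(y == lv[2])
  Sw <-(crossprod(sweep(x[y == lv[1], , drop = FALSE], 2, mu0)) +
         crossprod(sweep(x[y == lv[2], , drop = FALSE], 2, mu1))) /
    (n0 + n1 - 2)
  ch <- tryCatch(chol(Sw), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) *
        max(diag(ch))) {
    Sw <- Sw + (1e-6 * sum(diag(Sw)) / p) * diag(p)
    ch <- chol(Sw)
    ridged <- TRUE
  }
  w <- backsolve(ch, backsolve(ch, mu1 - mu0, transpose = TRUE))
  b <- -sum(w * (mu0 + mu1)) / 2 + log(n1 / n0)
  structure(list(w = w, b = b, classes = lv, means = rbind(mu0, mu1),
                 priors = c(n0, n1) / (n0 + n1), ridged = ridged),
            class = "lda_discriminant")
}

lda_score <- function(fit, x) {
  x <- as.matrix(x)
  if (!is.null(fit$ovr))
    return(sapply(fit$ovr, function(f) drop(x %*% f$w) + f$b))
  drop(x %*% fit$w) + fit$b
}

# ---- MF ------------------------------------------------------------------

#' Means-field (MF) classifier
#'
#' Fits the field of power means per class ([compute_means_field()], or
#' [robust_means_field()] when `robust = TRUE`), computes the squared
#' affine-invariant distances of every training trial to every mean
#' ([mf_features()]) and trains a closed-form linear discriminant
#' ([lda_fit()]) on those features. Unlike MDM/MDMF, which use only the
#' minimum distance, the discriminant can learn an arbitrary linear
#' function of all distances in the field. Fully deterministic.
#'
#' @inheritParams mdmf
#' @return object of class `mf` with elements `field`, `lda`, `classes`.
#' @export
mf <- function(set, h_values = default_h_field(), tol = 1e-7,
               maxit = 150L, robust = FALSE, z_threshold = 2.5,
               max_refinements = 4L, min_retained = 2L) {
  check_set(set)
  if (is.null(set$labels) || nlevels(set$labels) < 2L)
    stop("labeled set with at least 2 classes required")
  field <- resolve_field(set, h_values, tol, maxit, robust,
                         z_threshold, max_refinements, min_retained)
  feats <- t(vapply(set$matrices, mf_features, field = field,
                    FUN.VALUE = numeric(length(field$classes) *
                                          length(field$h_values))))
  fit <- lda_fit(feats, set$labels)
  structure(list(field = field, lda = fit, classes = field$classes),
            class = "mf")
}

# ---- predict methods ------------------------------------------------------

as_matrix_list <- function(newdata) {
  if (inherits(newdata, "cov_set")) newdata$matrices
  else if (is.matrix(newdata)) list(newdata)
  else if (is.list(newdata)) newdata
  else stop("newdata must be a cov_set, matrix, or list of matrices")
}

finish_prediction <- function(classes, score_mat, binary_score) {
  # score_mat: trials x classes, larger = more that class; ties -> lower index
  cls <- classes[apply(score_mat, 1, which.max)]
  data.frame(class = factor(cls, levels = classes),
             score = binary_score, row.names = NULL)
}

#' @describeIn mdm predict classes and scores for new trials. Returns a
#'   data frame with `class` and, for two classes, `score` = squared
#'   distance to the first-class mean minus squared distance to the
#'   second-class mean (larger = second class).
#' @param object fitted model.
#' @param newdata [cov_set()], single SPD matrix, or list of matrices.
#' @param ... unused.
#' @export
predict.mdm <- function(object, newdata, ...) {
  mats <- as_matrix_list(newdata)
  field <- object$field
  d2 <- t(vapply(mats, function(C) {
    vapply(field$classes, function(cl)
      airm_distance(C, field$means[[cl]][[h_key(0)]])^2, numeric(1))
  }, numeric(length(field$classes))))
  score <- if (length(field$classes) == 2L) d2[, 1] - d2[, 2] else NA_real_
  finish_prediction(field$classes, -d2, score)
}

#' @describeIn mdmf predict by the globally nearest mean in the field;
#'   binary score = min over h of the squared distance to the first class's
#'   means minus the same minimum for the second class.
#' @param object fitted model.
#' @param newdata [cov_set()], single SPD matrix, or list of matrices.
#' @param ... unused.
#' @export
predict.mdmf <- function(object, newdata, ...) {
  mats <- as_matrix_list(newdata)
  field <- object$field
  dmin <- t(vapply(mats, function(C) {
    vapply(field$classes, function(cl) min(class_sqdists(field, cl, C)),
           numeric(1))
  }, numeric(length(field$classes))))
  score <- if (length(field$classes) == 2L) dmin[, 1] - dmin[, 2] else
    NA_real_
  finish_prediction(field$classes, -dmin, score)
}

#' @describeIn mf predict via the linear discriminant on squared-distance
#'   features; binary score is the signed LDA score (larger = second
#'   class).
#' @param object fitted model.
#' @param newdata [cov_set()], single SPD matrix, or list of matrices.
#' @param ... unused.
#' @export
predict.mf <- function(object, newdata, ...) {
  mats <- as_matrix_list(newdata)
  feats <- t(vapply(mats, mf_features, field = object$field,
                    FUN.VALUE = numeric(length(object$classes) *
                                          length(object$field$h_values))))
  s <- lda_score(object$lda, feats)
  if (is.matrix(s)) {                       # one-versus-rest, > 2 classes
    finish_prediction(object$classes, s, NA_real_)
  } else {
    finish_prediction(object$classes, cbind(-s, s), s)
  }
}

#' @export
print.mdm <- function(x, ...) {
  cat("Minimum distance to mean (MDM) classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  covariance dimension: %dx%d\n", x$field$dim, x$field$dim))
  invisible(x)
}

#' @export
print.mdmf <- function(x, ...) {
  cat("Minimum distance to means field (MDMF) classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  h:", paste(x$field$h_values, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mf <- function(x, ...) {
  cat("Means field (MF) classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  h:", paste(x$field$h_values, collapse = ", "), "\n")
  cat(sprintf("  feature length: %d squared distances\n",
              length(x$classes) * length(x$field$h_values)))
  invisible(x)
}

#' @export
summary.mf <- function(object, ...) {
  print(object)
  d <- object$field$diagnostics
  cat("Mean-solver diagnostics (iterations per class and h):\n")
  print(stats::xtabs(iterations ~ class + h, data = d))
  invisible(object)
}
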