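# ---- SPD validation -------------------------------------------------------

#' Validate a symmetric positive-definite matrix
#'
#' Checks symmetry (relative asymmetry below `tol`) and strict positive
#' definiteness, and returns the symmetrized matrix `(S + t(S))/2`.
#' Asymmetry above tolerance or a non-positive eigenvalue is an error,
#' never a silent repair.
#'
#' @param S square numeric matrix.
#' @param tol relative symmetry tolerance.
#' @return the symmetrized matrix, invisibly usable as SPD.
#' @export
validate_spd <- function(S, tol = 1e-10) {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S))
    stop("input must be a square numeric matrix")
  nrmS <- sqrt(sum(S^2))
  asym <- sqrt(sum((S - t(S))^2))
  if (asym > tol * max(nrmS, 1))
    stop(sprintf("matrix is not symmetric (relative asymmetry %.3e)",
                 asym / max(nrmS, 1)))
  S <- (S + t(S)) / 2
  lam_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (!(lam_min > 0))
    stop(sprintf("matrix is not positive definite (smallest eigenvalue %.6e)",
                 lam_min))
  S
}

is_spd <- function(S, tol = 1e-10) {
  !inherits(try(validate_spd(S, tol), silent = TRUE), "try-error")
}

# ---- Symmetric matrix functions ------------------------------------------

sym_fun <- function(S, f) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

#' Matrix power of an SPD matrix
#'
#' Computes \eqn{S^t = U \mathrm{diag}(\lambda^t) U^\top} from the symmetric
#' eigendecomposition. Defined and SPD for any real exponent.
#'
#' @param S SPD matrix.
#' @param t real exponent.
#' @return SPD matrix \eqn{S^t}.
#' @export
sym_power <- function(S, t) {
  S <- validate_spd(S)
  P <- sym_fun(S, function(l) l^t)
  (P + t(P)) / 2
}

sym_log <- function(S) {
  L <- sym_fun(S, log)
  (L + t(L)) / 2
}

sym_exp <- function(S) {
  E <- sym_fun(S, exp)
  (E + t(E)) / 2
}

# ---- Affine-invariant metric ---------------------------------------------

#' Affine-invariant (Fisher-Rao) distance between SPD matrices
#'
#' \eqn{d(A,B) = \lVert \log(A^{-1/2} B A^{-1/2}) \rVert_F}, computed from
#' the generalized eigenvalues of the pair via a Cholesky whitening.
#' Invariant under congruence \eqn{C \mapsto F C F^\top} and inversion.
#'
#' @param A,B SPD matrices of the same dimension.
#' @return nonnegative scalar distance.
#' @export
airm_distance <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("dimension mismatch")
  U <- chol((A + t(A)) / 2)              # A = U'U
  Ui <- backsolve(U, diag(nrow(A)))
  M <- t(Ui) %*% ((B + t(B)) / 2) %*% Ui
  lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam <= 0)) stop("arguments must be positive definite")
  sqrt(sum(log(lam)^2))
}

#' Point along the affine-invariant geodesic
#'
#' Returns \eqn{A \#_t B = A^{1/2} (A^{-1/2} B A^{-1/2})^t A^{1/2}}.
#' `t = 0` gives `A`, `t = 1` gives `B`, `t = 1/2` the two-matrix
#' geometric mean.
#'
#' @param A,B SPD matrices of the same dimension.
#' @param t interpolation parameter in `[0, 1]` (any real accepted).
#' @return SPD matrix on the geodesic.
#' @export
geodesic_point <- function(A, B, t) {
  if (!all(dim(A) == dim(B))) stop("dimension mismatch")
  Ah <- sym_power(A, 0.5)
  Aih <- sym_power(A, -0.5)
  M <- Aih %*% ((B + t(B)) / 2) %*% Aih
  G <- Ah %*% sym_fun((M + t(M)) / 2, function(l) l^t) %*% Ah
  (G + t(G)) / 2
}

# ---- Shrinkage covariance estimation -------------------------------------

#' Oracle Approximating Shrinkage covariance of an epoch
#'
#' Estimates the channel covariance of a single epoch (channels x samples
#' matrix, assumed zero-mean after band-pass filtering; divisor `T`) and
#' shrinks it toward the scaled identity with the closed-form OAS
#' coefficient, guaranteeing a positive-definite output even for
#' rank-deficient sample covariances.
#'
#' @param x numeric matrix, channels x time samples (at least 2 samples).
#' @return SPD covariance matrix, channels x channels.
#' @export
oas_covariance <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("epoch must be a numeric matrix")
  n <- nrow(x)
  T_ <- ncol(x)
  if (n < 1L || T_ < 2L) stop("epoch needs at least 1 channel and 2 samples")
  S <- tcrossprod(x) / T_
  trS <- sum(diag(S))
  if (trS <= .Machine$double.eps)
    stop("zero-variance epoch: covariance undefined up to scale")
  trS2 <- sum(S^2)
  num <- (1 - 2 / n) * trS2 + trS^2
  den <- (T_ + 1 - 2 / n) * (trS2 - trS^2 / n)
  rho <- if (den <= 0) 1 else min(1, num / den)
  mu <- trS / n
  C <- (1 - rho) * S + rho * mu * diag(n)
  (C + t(C)) / 2
}

# ---- Trial covariance sets -----------------------------------------------

#' Labeled collection of SPD trial covariance matrices
#'
#' @param matrices list of SPD matrices (or a trials x n x n array), all
#'   of one dimension.
#' @param labels class identifier per matrix (coerced to factor); may be
#'   `NULL` for unlabeled uses.
#' @param weights positive weight per matrix; default uniform. Weights are
#'   renormalized to sum to one within each use.
#' @param validate check every matrix for the SPD invariants.
#' @return object of class `cov_set`.
#' @export
cov_set <- function(matrices, labels = NULL, weights = NULL, validate = TRUE) {
  if (is.array(matrices) && length(dim(matrices)) == 3L)
    matrices <- lapply(seq_len(dim(matrices)[1]),
                       function(k) matrices[k, , , drop = TRUE])
  if (!is.list(matrices) || length(matrices) == 0L)
    stop("matrices must be a non-empty list or 3-d array")
  n <- nrow(matrices[[1]])
  if (any(vapply(matrices, function(m) !all(dim(m) == c(n, n)), logical(1))))
    stop("all matrices must share one dimension")
  if (validate) matrices <- lapply(matrices, validate_spd)
  K <- length(matrices)
  if (!is.null(labels)) {
    if (length(labels) != K) stop("labels length must match matrices")
    labels <- factor(labels)
  }
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (length(weights) != K || any(weights <= 0))
    stop("weights must be positive, one per matrix")
  weights <- weights / sum(weights)
  structure(list(matrices = matrices, labels = labels, weights = weights,
                 dim = n),
            class = "cov_set")
}

#' @export
length.cov_set <- function(x) length(x$matrices)

#' @export
print.cov_set <- function(x, ...) {
  cat(sprintf("<cov_set> %d trials of %dx%d SPD matrices\n",
              length(x), x$dim, x$dim))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

subset_cov_set <- function(set, idx) {
  cov_set(set$matrices[idx],
          labels = if (!is.null(set$labels)) set$labels[idx],
          weights = set$weights[idx], validate = FALSE)
}

split_by_class <- function(set) {
  if (is.null(set$labels)) stop("labeled set required")
  lapply(levels(set$labels), function(lv) {
    idx <- which(set$labels == lv)
    if (length(idx) == 0L) stop(sprintf("class '%s' has zero trials", lv))
    subset_cov_set(set, idx)
  })
}

#' Covariance set from epoched signals
#'
#' Applies [oas_covariance()] to each epoch of an epoch set.
#'
#' @param epochs object of class `epoch_set` (see
#'   [make_mixed_source_epochs()]) or a list of channels x samples matrices.
#' @param labels labels when `epochs` is a plain list.
#' @return a [cov_set()].
#' @export
cov_set_from_epochs <- function(epochs, labels = NULL) {
  if (inherits(epochs, "epoch_set")) {
    labels <- epochs$labels
    epochs <- epochs$epochs
  }
  cov_set(lapply(epochs, oas_covariance), labels = labels, validate = FALSE)
}
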