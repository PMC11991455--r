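# Power means of SPD matrices over the exponent field h in [-1, 1].
#
# h = 1 is the arithmetic mean, h = -1 the harmonic mean, and the geometric
# (Karcher) mean is the h -> 0 limit. Means for h in (0, 1] solve the
# self-consistency equation P = sum_k w_k (P #_h C_k); negative h is handled
# by the duality P_{-h}({C_k}) = [P_h({C_k^{-1}})]^{-1}.

#' Default exponent field
#'
#' The eleven power-mean exponents used by the means-field classifiers:
#' \{-1, -0.75, -0.5, -0.25, -0.1, 0, 0.1, 0.25, 0.5, 0.75, 1\}.
#' @return numeric vector of length 11, ascending.
#' @export
default_h_field <- function() {
  c(-1, -0.75, -0.5, -0.25, -0.1, 0, 0.1, 0.25, 0.5, 0.75, 1)
}

check_set <- function(set) {
  if (!inherits(set, "cov_set")) stop("expected a cov_set")
  if (length(set) == 0L) stop("empty covariance set")
  invisible(set)
}

#' Weighted arithmetic mean of a covariance set
#'
#' \eqn{\sum_k w_k C_k}; the power mean at h = 1.
#' @param set a [cov_set()].
#' @return SPD matrix.
#' @export
arithmetic_mean <- function(set) {
  check_set(set)
  M <- Reduce(`+`, Map(`*`, set$matrices, set$weights / sum(set$weights)))
  (M + t(M)) / 2
}

#' Weighted harmonic mean of a covariance set
#'
#' \eqn{(\sum_k w_k C_k^{-1})^{-1}}; the power mean at h = -1.
#' @param set a [cov_set()].
#' @return SPD matrix.
#' @export
harmonic_mean <- function(set) {
  check_set(set)
  w <- set$weights / sum(set$weights)
  M <- Reduce(`+`, Map(function(C, wk) wk * chol2inv(chol(C)),
                       set$matrices, w))
  Mi <- chol2inv(chol((M + t(M)) / 2))
  (Mi + t(Mi)) / 2
}

inverse_set <- function(set) {
  cov_set(lapply(set$matrices, function(C) {
    Ci <- chol2inv(chol(C))
    (Ci + t(Ci)) / 2
  }), labels = set$labels, weights = set$weights, validate = FALSE)
}

#' Geometric (Karcher) mean of a covariance set
#'
#' Fixed-point iteration
#' \eqn{G \leftarrow G^{1/2} \exp(\epsilon \sum_k w_k \log(G^{-1/2} C_k
#' G^{-1/2})) G^{1/2}} with initial step \eqn{\epsilon = 1}, halved whenever
#' the residual increases. Convergence is declared when the Frobenius norm of
#' the weighted log-sum, scaled by \eqn{\sqrt{n}}, falls below `tol`. The
#' Karcher mean is unique on the SPD manifold, so the result does not depend
#' on the initialization.
#'
#' @param set a [cov_set()].
#' @param tol convergence tolerance (default 1e-7).
#' @param maxit maximum iterations (default 150).
#' @param init optional SPD warm start; default is the geodesic midpoint of
#'   the arithmetic and harmonic means.
#' @return SPD matrix with attributes `iterations` and `residual`.
#' @export
geometric_mean <- function(set, tol = 1e-7, maxit = 150L, init = NULL) {
  check_set(set)
  w <- set$weights / sum(set$weights)
  n <- set$dim
  if (length(set) == 1L) {
    G <- set$matrices[[1]]
    attr(G, "iterations") <- 0L
    attr(G, "residual") <- 0
    return(G)
  }
  G <- if (is.null(init)) {
    geodesic_point(arithmetic_mean(set), harmonic_mean(set), 0.5)
  } else (init + t(init)) / 2
  eps <- 1
  prev_res <- Inf
  for (it in seq_len(maxit)) {
    Gh <- sym_fun(G, sqrt)
    Gih <- sym_fun(G, function(l) 1 / sqrt(l))
    L <- matrix(0, n, n)
    for (k in seq_along(w)) {
      M <- Gih %*% set$matrices[[k]] %*% Gih
      L <- L + w[k] * sym_log((M + t(M)) / 2)
    }
    res <- sqrt(sum(L^2)) / sqrt(n)
    if (res < tol) {
      attr(G, "iterations") <- it - 1L
      attr(G, "residual") <- res
      return(G)
    }
    if (res > prev_res) eps <- eps / 2
    prev_res <- res
    G <- Gh %*% sym_exp(eps * L) %*% Gh
    G <- (G + t(G)) / 2
  }
  stop(sprintf("geometric mean did not converge in %d iterations (residual %.3e)",
               maxit, prev_res))
}

# Multiplicative fixed point on a square-root factor X for h in (0, 1]:
# H = sum_k w_k (X C_k X')^h drives the update X <- H^(-phi) X with step
# phi = 0.375/h; at convergence H = I and P = (X'X)^(-1).
power_mean_pos <- function(set, h, tol, maxit, init) {
  w <- set$weights / sum(set$weights)
  n <- set$dim
  P0 <- if (is.null(init)) arithmetic_mean(set) else (init + t(init)) / 2
  X <- sym_fun(P0, function(l) 1 / sqrt(l))
  phi <- 0.375 / h
  for (it in seq_len(maxit)) {
    H <- matrix(0, n, n)
    for (k in seq_along(w)) {
      M <- X %*% set$matrices[[k]] %*% t(X)
      H <- H + w[k] * sym_fun((M + t(M)) / 2, function(l) l^h)
    }
    res <- sqrt(sum((H - diag(n))^2)) / sqrt(n)
    if (res < tol) {
      P <- chol2inv(chol(crossprod(X)))
      P <- (P + t(P)) / 2
      attr(P, "iterations") <- it - 1L
      attr(P, "residual") <- res
      return(P)
    }
    X <- sym_fun((H + t(H)) / 2, function(l) l^(-phi)) %*% X
  }
  stop(sprintf("power mean (h = %g) did not converge in %d iterations (residual %.3e)",
               h, maxit, res))
}

#' Power mean of a covariance set
#'
#' For `h` in (0, 1] solves \eqn{P = \sum_k w_k (P \#_h C_k)} by a
#' multiplicative fixed-point iteration on a square-root factor; `h` in
#' [-1, 0) uses the duality with the mean of the inverses; `h = 0` dispatches
#' to [geometric_mean()].
#'
#' @param set a [cov_set()].
#' @param h exponent in `[-1, 1]`.
#' @param tol convergence tolerance (default 1e-7).
#' @param maxit maximum iterations (default 150).
#' @param init optional SPD warm start (in the original, non-inverted
#'   geometry for any sign of `h`).
#' @return SPD matrix with attributes `iterations` and `residual`.
#' @export
power_mean <- function(set, h, tol = 1e-7, maxit = 150L, init = NULL) {
  check_set(set)
  if (!is.numeric(h) || length(h) != 1L || h < -1 || h > 1)
    stop("h must be a single value in [-1, 1]")
  if (h == 0) return(geometric_mean(set, tol = tol, maxit = maxit, init = init))
  if (h > 0) return(power_mean_pos(set, h, tol, maxit, init))
  iinit <- if (!is.null(init)) {
    Ii <- chol2inv(chol((init + t(init)) / 2)); (Ii + t(Ii)) / 2
  }
  P <- power_mean_pos(inverse_set(set), -h, tol, maxit, iinit)
  Pi <- chol2inv(chol(P))
  Pi <- (Pi + t(Pi)) / 2
  attr(Pi, "iterations") <- attr(P, "iterations")
  attr(Pi, "residual") <- attr(P, "residual")
  Pi
}

# ---- Means field ----------------------------------------------------------

h_key <- function(h) formatC(h, format = "g")

#' Compute the field of power means, one per (class, h) pair
#'
#' Within each class, means for positive `h` are computed in decreasing order
#' starting from the arithmetic mean at h = 1, each solve warm-started at the
#' previous solution; negative `h` likewise in increasing order from the
#' harmonic mean at h = -1; the geometric mean (h = 0) is warm-started from
#' the mean at the smallest available |h|.
#'
#' @param set labeled [cov_set()] with at least one trial per class.
#' @param h_values exponents of the field (default [default_h_field()]).
#' @param tol,maxit solver controls.
#' @return object of class `means_field`: per-class lists of SPD means
#'   keyed by `h`, plus iteration diagnostics.
#' @export
compute_means_field <- function(set, h_values = default_h_field(),
                                tol = 1e-7, maxit = 150L) {
  check_set(set)
  if (is.null(set$labels)) stop("labeled set required")
  if (anyDuplicated(h_values)) stop("h_values must be distinct")
  if (any(h_values < -1 | h_values > 1)) stop("h_values must lie in [-1, 1]")
  classes <- levels(set$labels)
  by_class <- split_by_class(set)
  diagnostics <- list()
  means <- lapply(seq_along(classes), function(ci) {
    class_field(by_class[[ci]], h_values, tol, maxit)
  })
  names(means) <- classes
  diag_tab <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    d <- attr(means[[ci]], "diagnostics")
    d$class <- classes[ci]
    d
  }))
  for (ci in seq_along(means)) attr(means[[ci]], "diagnostics") <- NULL
  structure(list(means = means, classes = classes,
                 h_values = sort(h_values), dim = set$dim,
                 diagnostics = diag_tab),
            class = "means_field")
}

class_field <- function(cset, h_values, tol, maxit) {
  hs <- sort(h_values)
  out <- vector("list", length(hs))
  names(out) <- h_key(hs)
  diags <- data.frame(h = hs, iterations = NA_integer_, residual = NA_real_)
  pos <- sort(hs[hs > 0], decreasing = TRUE)
  neg <- sort(hs[hs < 0])
  store <- function(h, P) {
    key <- h_key(h)
    i <- which(diags$h == h)
    diags$iterations[i] <<- attr(P, "iterations") %||% 0L
    diags$residual[i] <<- attr(P, "residual") %||% 0
    attr(P, "iterations") <- NULL
    attr(P, "residual") <- NULL
    out[[key]] <<- P
  }
  prev <- NULL
  for (h in pos) {
    P <- if (h == 1) arithmetic_mean(cset) else
      power_mean(cset, h, tol, maxit, init = prev)
    store(h, P)
    prev <- P
  }
  prev <- NULL
  for (h in neg) {
    P <- if (h == -1) harmonic_mean(cset) else
      power_mean(cset, h, tol, maxit, init = prev)
    store(h, P)
    prev <- P
  }
  if (0 %in% hs) {
    nz <- hs[hs != 0]
    init <- if (length(nz)) out[[h_key(nz[which.min(abs(nz))])]]
    store(0, geometric_mean(cset, tol, maxit, init = init))
  }
  attr(out, "diagnostics") <- diags
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.means_field <- function(x, ...) {
  cat(sprintf("<means_field> %d classes x %d power means (%dx%d)\n",
              length(x$classes), length(x$h_values), x$dim, x$dim))
  cat("  h:", paste(x$h_values, collapse = ", "), "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# ---- Robust estimation ----------------------------------------------------

#' Standardized geodesic distances from a center
#'
#' Computes the affine-invariant distance of every trial to `center` and
#' returns the z-scores (sample standard deviation, divisor n - 1). If the
#' distances are essentially constant (sd < 1e-12) all z-scores are zero.
#'
#' @param set a [cov_set()] with at least two trials.
#' @param center SPD matrix.
#' @return numeric vector of z-scores, one per trial.
#' @export
standardized_distances <- function(set, center) {
  check_set(set)
  if (length(set) < 2L) stop("at least 2 trials required")
  d <- vapply(set$matrices, airm_distance, numeric(1), B = center)
  s <- stats::sd(d)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(d)))
  (d - mean(d)) / s
}

#' Robust power mean with iterative outlier trimming
#'
#' Repeats up to `max_refinements` times: estimate the mean on the retained
#' trials, flag trials whose standardized geodesic distance exceeds
#' `z_threshold`, remove them. Stops when no trial is flagged or when removal
#' would leave fewer than `min_retained` trials (removal is then skipped
#' entirely, not applied partially). Weights are renormalized over survivors.
#'
#' @param set a [cov_set()] with at least `min_retained` trials.
#' @param h power-mean exponent.
#' @param tol,maxit solver controls.
#' @param z_threshold outlier threshold on the standardized geodesic
#'   distance (default 2.5).
#' @param max_refinements maximum trimming rounds (default 4).
#' @param min_retained smallest admissible surviving set (default 2).
#' @return list with `mean` (SPD) and `retained` (surviving trial indices).
#' @export
robust_mean <- function(set, h = 0, tol = 1e-7, maxit = 150L,
                        z_threshold = 2.5, max_refinements = 4L,
                        min_retained = 2L) {
  check_set(set)
  if (z_threshold <= 0) stop("z_threshold must be positive")
  if (max_refinements < 1L) stop("max_refinements must be >= 1")
  if (length(set) < min_retained)
    stop(sprintf("need at least %d trials", min_retained))
  retained <- seq_len(length(set))
  removals <- 0L
  repeat {
    cur <- subset_cov_set(set, retained)
    m <- power_mean(cur, h, tol, maxit)
    if (removals >= max_refinements || length(retained) < 2L) break
    z <- standardized_distances(cur, m)
    out <- which(z > z_threshold)
    if (length(out) == 0L) break
    if (length(retained) - length(out) < min_retained) break
    retained <- retained[-out]
    removals <- removals + 1L
  }
  list(mean = m, retained = retained)
}

#' Robust means field
#'
#' Per class, the outlier screen of [robust_mean()] is run once against the
#' class geometric mean (h = 0); the surviving trials are then used to
#' compute the whole field with warm starts. On an outlier-free set this
#' equals [compute_means_field()] exactly.
#'
#' @inheritParams compute_means_field
#' @inheritParams robust_mean
#' @return a `means_field` with a `retained` attribute listing surviving
#'   trial indices (into the input set) per class.
#' @export
robust_means_field <- function(set, h_values = default_h_field(),
                               tol = 1e-7, maxit = 150L,
                               z_threshold = 2.5, max_refinements = 4L,
                               min_retained = 2L) {
  check_set(set)
  if (is.null(set$labels)) stop("labeled set required")
  classes <- levels(set$labels)
  keep <- integer(0)
  retained_by_class <- list()
  for (lv in classes) {
    idx <- which(set$labels == lv)
    if (length(idx) == 0L) stop(sprintf("class '%s' has zero trials", lv))
    rm <- robust_mean(subset_cov_set(set, idx), h = 0, tol = tol,
                      maxit = maxit, z_threshold = z_threshold,
                      max_refinements = max_refinements,
                      min_retained = min_retained)
    retained_by_class[[lv]] <- idx[rm$retained]
    keep <- c(keep, idx[rm$retained])
  }
  keep <- sort(keep)
  field <- compute_means_field(subset_cov_set(set, keep), h_values,
                               tol, maxit)
  attr(field, "retained") <- retained_by_class
  field
}
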