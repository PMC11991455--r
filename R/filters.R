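# Dimensionality-reducing spatial filters for covariance-based decoding.
# Classical two-class CSP by generalized eigendecomposition, Pham's
# approximate joint diagonalization, and the two-stage adaptive double CSP
# (Euclidean-mean GEVD to 28 components, then geometric-mean AJD to 10).

new_spatial_filter <- function(W, stage_log = list()) {
  structure(list(W = W, stage_log = stage_log), class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("<spatial_filter> %d x %d\n", nrow(x$W), ncol(x$W)))
  for (s in x$stage_log)
    cat(sprintf("  %s: %d -> %d (%s)\n", s$stage, s$from, s$to, s$method))
  invisible(x)
}

# Largest-magnitude entry of each row made positive; rows unit-normalized.
normalize_rows <- function(W) {
  t(apply(W, 1, function(r) {
    r <- r / sqrt(sum(r^2))
    if (r[which.max(abs(r))] < 0) -r else r
  }))
}

gevd_csp <- function(M1, M2) {
  # generalized eigenproblem M1 v = lambda (M1 + M2) v via whitening
  Mt <- M1 + M2
  W0 <- sym_fun(Mt, function(l) 1 / sqrt(l))
  e <- eigen((W0 %*% M1 %*% W0 + t(W0 %*% M1 %*% W0)) / 2, symmetric = TRUE)
  list(filters = t(e$vectors) %*% W0, lambda = e$values)
}

#' CSP spatial filters from class mean covariances
#'
#' Two-class `euclid_gevd`: solves the generalized eigenproblem
#' \eqn{M_1 v = \lambda (M_1 + M_2) v}, orders the eigenvectors by
#' \eqn{|\lambda - 1/2|} descending and keeps the top `n_filters` from each
#' side of 1/2 (variance-contrast filters for each class). `geom_ajd`
#' (any number of classes): approximately jointly diagonalizes the class
#' means with [pham_ajd()] and keeps the `n_filters * n_classes` rows with
#' the largest between-class dispersion of `log(v' M_c v)`.
#'
#' @param class_means list of SPD class mean covariances (common dimension).
#' @param n_filters filters retained per class.
#' @param method `"euclid_gevd"` (two classes) or `"geom_ajd"`.
#' @return a `spatial_filter` with `2 * n_filters` (or
#'   `n_filters * n_classes`) unit-norm rows.
#' @export
csp_filters <- function(class_means, n_filters,
                        method = c("euclid_gevd", "geom_ajd")) {
  method <- match.arg(method)
  nc <- length(class_means)
  if (nc < 2L) stop("at least 2 class means required")
  n <- nrow(class_means[[1]])
  if (n_filters * nc > n)
    stop(sprintf("n_filters (%d) too large for dimension %d with %d classes",
                 n_filters, n, nc))
  if (method == "euclid_gevd") {
    if (nc != 2L) stop("euclid_gevd is defined for exactly 2 classes")
    g <- gevd_csp(class_means[[1]], class_means[[2]])
    sep <- abs(g$lambda - 0.5)
    hi <- which(g$lambda >= 0.5)
    lo <- which(g$lambda < 0.5)
    pick_side <- function(side) side[order(sep[side],
                                           decreasing = TRUE)][seq_len(
                                             min(n_filters, length(side)))]
    sel <- c(pick_side(hi), pick_side(lo))
    # degenerate ties (all lambda = 0.5): fill in eigenvalue-index order
    if (length(sel) < 2L * n_filters) {
      extra <- setdiff(seq_len(n), sel)
      sel <- c(sel, extra[seq_len(2L * n_filters - length(sel))])
    }
    sel <- sel[order(sep[sel], decreasing = TRUE)]
    W <- g$filters[sel, , drop = FALSE]
  } else {
    B <- pham_ajd(class_means)
    sc <- ajd_discriminability(B, class_means)
    sel <- order(sc, decreasing = TRUE)[seq_len(n_filters * nc)]
    W <- B[sort(sel), , drop = FALSE]
    W <- W[order(sc[sort(sel)], decreasing = TRUE), , drop = FALSE]
  }
  new_spatial_filter(normalize_rows(W))
}

# Between-class dispersion of the log component variances log(v' M_c v):
# components whose variance profile differs most across classes rank first.
ajd_discriminability <- function(B, class_means) {
  lv <- sapply(class_means, function(M) log(rowSums((B %*% M) * B)))
  apply(lv, 1, stats::var)
}

#' Pham's approximate joint diagonalization
#'
#' Finds an invertible matrix `B` minimizing the log-likelihood
#' joint-diagonality criterion
#' \eqn{\sum_k w_k [\log\det \mathrm{diag}(B C_k B') - \log\det(B C_k B')]}
#' by iterative pairwise Newton sweeps; the criterion is monitored and the
#' pairwise step is halved if it would increase. Rows of `B` are
#' unit-normalized (the criterion is invariant to row rescaling).
#'
#' @param matrices list of SPD matrices of one dimension (at least 2).
#' @param weights positive weights, default uniform.
#' @param tol stop when the criterion decrease over a sweep falls below
#'   `tol`.
#' @param max_sweeps maximum number of full pairwise sweeps.
#' @return invertible matrix `B` with attribute `criterion`.
#' @export
pham_ajd <- function(matrices, weights = NULL, tol = 1e-10,
                     max_sweeps = 100L) {
  K <- length(matrices)
  if (K < 2L) stop("at least 2 matrices required")
  n <- nrow(matrices[[1]])
  if (is.null(weights)) weights <- rep(1 / K, K)
  weights <- weights / sum(weights)
  # whitening of the weighted arithmetic mean as starting point
  M0 <- Reduce(`+`, Map(`*`, matrices, weights))
  B <- sym_fun(M0, function(l) 1 / sqrt(l))
  D <- array(0, c(n, n, K))
  for (k in seq_len(K)) D[, , k] <- B %*% matrices[[k]] %*% t(B)
  crit <- function() {
    v <- 0
    for (k in seq_len(K)) {
      dk <- D[, , k]
      v <- v + weights[k] *
        (sum(log(diag(dk))) - determinant(dk, logarithm = TRUE)$modulus[1])
    }
    v
  }
  cur <- crit()
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      c1 <- D[i, i, ]; c2 <- D[j, j, ]; c12 <- D[i, j, ]
      g_a <- sum(weights * c12 / c1)
      g_b <- sum(weights * c12 / c2)
      q_a <- sum(weights * c2 / c1)
      q_b <- sum(weights * c1 / c2)
      det2 <- q_a * q_b - 1
      if (det2 < 1e-12) next
      a <- (g_b - q_b * g_a) / det2
      b <- (g_a - q_a * g_b) / det2
      step <- 1
      repeat {
        aa <- step * a; bb <- step * b
        if (abs(1 - aa * bb) < 1e-8) { step <- step / 2; next }
        # criterion change restricted to the (i, j) pair
        d1 <- c1 + 2 * aa * c12 + aa^2 * c2
        d2 <- c2 + 2 * bb * c12 + bb^2 * c1
        if (any(d1 <= 0) || any(d2 <= 0)) { step <- step / 2; next }
        delta <- sum(weights * (log(d1 / c1) + log(d2 / c2))) -
          2 * log(abs(1 - aa * bb))
        if (delta <= 1e-14 || step < 1e-8) break
        step <- step / 2
      }
      if (delta > 1e-14) next
      Tm <- rbind(c(1, aa), c(bb, 1))
      B[c(i, j), ] <- Tm %*% B[c(i, j), , drop = FALSE]
      for (k in seq_len(K)) {
        D[c(i, j), , k] <- Tm %*% D[c(i, j), , k]
        D[, c(i, j), k] <- D[, c(i, j), k] %*% t(Tm)
      }
      cur <- cur + delta
    }
    cur <- crit()
    if (prev - cur < tol) {
      B <- normalize_rows(B)
      attr(B, "criterion") <- cur
      attr(B, "sweeps") <- sweep
      return(B)
    }
  }
  stop(sprintf("pham_ajd did not converge in %d sweeps (criterion %.6e)",
               max_sweeps, cur))
}

#' Fit the two-stage adaptive double CSP (ADCSP) filter
#'
#' Stage 1 (entered only when the covariance dimension is at least
#' `stage1_dim`, default 28): class means by the weighted arithmetic mean,
#' filters from a generalized eigendecomposition (two classes) or Pham AJD
#' of the class means (more classes), reducing to `stage1_dim`. Stage 2
#' (after stage 1, entered when the current dimension is at least
#' `stage2_dim`, default 10): class means by the geometric mean, filters by
#' [pham_ajd()] ranked by between-class discriminability, reducing to
#' `stage2_dim`. Inputs below `stage2_dim` channels pass through an identity
#' filter. The two-stage procedure guarantees an output dimension of at most
#' `stage2_dim`.
#'
#' @param set labeled [cov_set()] with at least 2 classes.
#' @param stage1_dim,stage2_dim stage entry thresholds and target
#'   dimensions (defaults 28 and 10).
#' @param tol,maxit geometric-mean solver controls for stage 2.
#' @return a `spatial_filter`; `stage_log` records the dimensions traversed.
#' @export
adcsp_fit <- function(set, stage1_dim = 28L, stage2_dim = 10L,
                      tol = 1e-7, maxit = 150L) {
  check_set(set)
  if (is.null(set$labels) || nlevels(set$labels) < 2L)
    stop("labeled set with at least 2 classes required")
  n <- set$dim
  W <- diag(n)
  log <- list()
  cur <- set
  d <- n
  if (d >= stage1_dim) {
    by_class <- split_by_class(cur)
    means <- lapply(by_class, arithmetic_mean)
    if (length(means) == 2L) {
      g <- gevd_csp(means[[1]], means[[2]])
      sel <- order(abs(g$lambda - 0.5), decreasing = TRUE)[seq_len(stage1_dim)]
      W1 <- normalize_rows(g$filters[sel, , drop = FALSE])
    } else {
      B <- pham_ajd(means)
      sc <- ajd_discriminability(B, means)
      W1 <- B[order(sc, decreasing = TRUE)[seq_len(stage1_dim)], ,
              drop = FALSE]
      W1 <- normalize_rows(W1)
    }
    W <- W1
    log[[length(log) + 1L]] <- list(stage = "stage1", from = d,
                                    to = stage1_dim,
                                    method = if (length(means) == 2L)
                                      "euclid_gevd" else "euclid_ajd")
    cur <- apply_filter(new_spatial_filter(W1), cur)
    d <- stage1_dim
  }
  if (d >= stage2_dim) {
    by_class <- split_by_class(cur)
    means <- lapply(by_class, geometric_mean, tol = tol, maxit = maxit)
    means <- lapply(means, function(m) {
      attributes(m)[c("iterations", "residual")] <- NULL; m
    })
    B <- pham_ajd(means)
    sc <- ajd_discriminability(B, means)
    W2 <- B[order(sc, decreasing = TRUE)[seq_len(stage2_dim)], ,
            drop = FALSE]
    W2 <- normalize_rows(W2)
    W <- W2 %*% W
    log[[length(log) + 1L]] <- list(stage = "stage2", from = d,
                                    to = stage2_dim, method = "geom_ajd")
    d <- stage2_dim
  }
  new_spatial_filter(W, log)
}

#' Apply a spatial filter to SPD matrices by congruence
#'
#' Returns \eqn{W C W'} for a single SPD matrix, or the filtered
#' [cov_set()] when given a set. Congruence by a full-row-rank matrix
#' preserves positive definiteness.
#'
#' @param filter a `spatial_filter`.
#' @param C SPD matrix or [cov_set()].
#' @return filtered SPD matrix or `cov_set`.
#' @export
apply_filter <- function(filter, C) {
  W <- filter$W
  if (inherits(C, "cov_set")) {
    if (ncol(W) != C$dim) stop("dimension mismatch")
    return(cov_set(lapply(C$matrices, function(m) {
      M <- W %*% m %*% t(W); (M + t(M)) / 2
    }), labels = C$labels, weights = C$weights, validate = FALSE))
  }
  if (ncol(W) != nrow(C)) stop("dimension mismatch")
  M <- W %*% C %*% t(W)
  (M + t(M)) / 2
}
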