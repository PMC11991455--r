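# Synthetic data with known ground truth, so every stage (shrinkage
# covariance estimation, spatial filters, means, classifiers, statistics)
# is testable without recorded EEG. Two generators:
#
#  * clouds of SPD matrices concentrated around class centers, sampled in
#    the tangent space (log-normal on the manifold) so center and
#    dispersion are independently controllable, with optional planted
#    outliers generated by inflating the dispersion (the noisy-trial
#    failure mode the robust estimator targets);
#  * raw two-class multichannel epochs from a linear mixing of latent
#    sources whose variances differ by class, plus white sensor noise.
#
# All generators are pure functions of their arguments including the seed.

rand_sym <- function(n, scale) {
  S <- matrix(0, n, n)
  S[upper.tri(S)] <- stats::rnorm(n * (n - 1) / 2, sd = scale)
  S <- S + t(S)
  diag(S) <- stats::rnorm(n, sd = scale)
  S
}

#' Sample a cloud of SPD matrices around a center
#'
#' Each trial is \eqn{C^{1/2} \exp(S) C^{1/2}} with `S` a random symmetric
#' matrix with independent entries of scale `sigma` (tangent-space
#' sampling). `sigma = 0` returns `n` copies of the center.
#'
#' @param center SPD center matrix.
#' @param sigma tangent-space dispersion, nonnegative.
#' @param n number of trials (at least 1).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param labels optional labels for the resulting set.
#' @return a [cov_set()].
#' @export
sample_spd_cloud <- function(center, sigma, n, seed = 1L, labels = NULL) {
  if (n < 1L) stop("n must be at least 1")
  if (sigma < 0) stop("sigma must be nonnegative")
  center <- validate_spd(center)
  ch <- sym_fun(center, sqrt)
  mats <- with_seed(seed, lapply(seq_len(n), function(i) {
    M <- ch %*% sym_exp(rand_sym(nrow(center), sigma)) %*% ch
    (M + t(M)) / 2
  }))
  cov_set(mats, labels = labels, validate = FALSE)
}

#' Two-class SPD cloud with controllable separation and planted outliers
#'
#' Class centers are placed `class_separation` apart (affine-invariant
#' distance) symmetrically along a seeded random geodesic through the
#' identity. Per class, `n_trials_per_class` trials are sampled with the
#' class dispersion; a fraction `outlier_fraction` of them is replaced by
#' trials drawn at `outlier_magnitude` times the dispersion. Ground-truth
#' centers and outlier indices are attached as attributes.
#'
#' @param n_channels matrix dimension.
#' @param n_trials_per_class trials per class.
#' @param dispersion tangent-space noise scale; length 1 or one per class.
#' @param class_separation geodesic distance between the class centers.
#' @param outlier_fraction fraction of trials per class replaced by
#'   outliers, in `[0, 0.5)`.
#' @param outlier_magnitude dispersion inflation factor for outliers (> 1).
#' @param seed integer seed.
#' @return labeled [cov_set()] with attributes `centers` (list of the two
#'   true centers) and `outliers` (planted trial indices).
#' @export
make_two_class_set <- function(n_channels = 4L, n_trials_per_class = 40L,
                               dispersion = 0.3, class_separation = 1,
                               outlier_fraction = 0, outlier_magnitude = 10,
                               seed = 1L) {
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    stop("outlier_fraction must be in [0, 0.5)")
  if (outlier_fraction > 0 && outlier_magnitude <= 1)
    stop("outlier_magnitude must exceed 1")
  disp <- rep_len(dispersion, 2L)
  dir <- with_seed(seed, rand_sym(n_channels, 1))
  dir <- dir / sqrt(sum(dir^2))
  centers <- list(sym_exp(-class_separation / 2 * dir),
                  sym_exp(class_separation / 2 * dir))
  n <- n_trials_per_class
  n_out <- floor(outlier_fraction * n)
  mats <- list(); labels <- character(0); outliers <- integer(0)
  for (cl in 1:2) {
    clean <- sample_spd_cloud(centers[[cl]], disp[cl], n - n_out,
                              seed = seed + 17L * cl)
    mats <- c(mats, clean$matrices)
    if (n_out > 0) {
      bad <- sample_spd_cloud(centers[[cl]], disp[cl] * outlier_magnitude,
                              n_out, seed = seed + 17L * cl + 7L)
      outliers <- c(outliers, length(mats) + seq_len(n_out))
      mats <- c(mats, bad$matrices)
    }
    labels <- c(labels, rep(paste0("class", cl), n))
  }
  out <- cov_set(mats, labels = labels, validate = FALSE)
  attr(out, "centers") <- centers
  attr(out, "outliers") <- outliers
  out
}

#' Mixed-source epochs for a two-class event-related-desynchronization
#' analogue
#'
#' Latent sources are white Gaussian; a designated pair of discriminative
#' sources carries class-dependent variance (high/low swapped between the
#' classes, emulating lateralized sensorimotor power modulation), the rest
#' have unit variance in both classes. Sources are mixed by a seeded random
#' full-rank matrix and white sensor noise is added so that the average
#' per-channel signal-to-noise variance ratio equals `snr`. The true mixing
#' matrix and the discriminative source indices are attached for
#' filter-recovery tests.
#'
#' @param n_channels number of sensors.
#' @param n_sources number of latent sources (<= `n_channels`).
#' @param n_trials_per_class trials per class.
#' @param n_samples time samples per epoch.
#' @param snr average per-channel signal-to-noise variance ratio; `Inf`
#'   for noise-free epochs.
#' @param class_var variance of the discriminative sources in their strong
#'   class (weak class has `1/class_var`).
#' @param seed integer seed.
#' @return object of class `epoch_set`: list of channels x samples
#'   matrices, labels, and ground-truth attributes `mixing` and
#'   `discriminative`.
#' @export
make_mixed_source_epochs <- function(n_channels = 8L, n_sources = 4L,
                                     n_trials_per_class = 30L,
                                     n_samples = 256L, snr = 5,
                                     class_var = 4, seed = 1L) {
  if (n_sources > n_channels) stop("n_sources must not exceed n_channels")
  if (n_sources < 2L) stop("need at least 2 sources")
  disc <- c(1L, 2L)
  with_seed(seed, {
    A <- matrix(stats::rnorm(n_channels * n_sources), n_channels, n_sources)
    # class-wise source standard deviations: disc sources swap high/low
    sd_class <- list(c(sqrt(class_var), sqrt(1 / class_var),
                       rep(1, n_sources - 2L)),
                     c(sqrt(1 / class_var), sqrt(class_var),
                       rep(1, n_sources - 2L)))
    epochs <- list(); labels <- character(0)
    for (cl in 1:2) for (tr in seq_len(n_trials_per_class)) {
      s <- matrix(stats::rnorm(n_sources * n_samples), n_sources) *
        sd_class[[cl]]
      x <- A %*% s
      if (is.finite(snr)) {
        sig_var <- mean(rowMeans(x^2))
        x <- x + matrix(stats::rnorm(n_channels * n_samples,
                                     sd = sqrt(sig_var / snr)),
                        n_channels)
      }
      epochs[[length(epochs) + 1L]] <- x
      labels <- c(labels, paste0("class", cl))
    }
    structure(list(epochs = epochs, labels = factor(labels),
                   n_channels = n_channels, n_samples = n_samples),
              class = "epoch_set",
              mixing = A, discriminative = disc)
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs, %d channels x %d samples\n",
              length(x$epochs), x$n_channels, x$n_samples))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}
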