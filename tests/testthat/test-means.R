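# Power means over the exponent field: closed-form endpoints, scalar
# reduction, duality, convergence contracts, warm-start scheduling, and the
# robust (outlier-trimming) estimation loop.

test_that("arithmetic and harmonic means match their closed forms", {
  s <- cov_set(list(diag(c(1, 1)), diag(c(3, 5))))
  expect_equal(arithmetic_mean(s), diag(c(2, 3)))
  s1 <- cov_set(list(diag(2) * 2))
  expect_equal(arithmetic_mean(s1), diag(2) * 2)
  sw <- cov_set(list(diag(2), 3 * diag(2)), weights = c(0.25, 0.75))
  expect_equal(arithmetic_mean(sw), 2.5 * diag(2))

  sh <- cov_set(list(diag(c(1, 1)), diag(c(3, 1))))
  expect_equal(harmonic_mean(sh), diag(c(1.5, 1)), tolerance = 1e-12)
  expect_error(arithmetic_mean(cov_set(list())), "non-empty|empty")
})

test_that("harmonic <= geometric <= arithmetic in Loewner order", {
  set.seed(10)
  for (i in 1:5) {
    s <- rand_spd_set(6, 4)
    H <- harmonic_mean(s); A <- arithmetic_mean(s); G <- geometric_mean(s)
    lam <- function(M) min(eigen(M, symmetric = TRUE,
                                 only.values = TRUE)$values)
    expect_gte(lam(A - G), -1e-8)
    expect_gte(lam(G - H), -1e-8)
    expect_gte(lam(A - H), -1e-8)
  }
})

test_that("geometric mean: identical set, two-matrix closed form, commuting", {
  set.seed(11)
  C <- rand_spd(4)
  s <- cov_set(list(C, C, C), validate = FALSE)
  expect_equal(geometric_mean(s), C, tolerance = 1e-7,
               ignore_attr = TRUE)

  A <- rand_spd(4); B <- rand_spd(4)
  expect_equal(geometric_mean(cov_set(list(A, B), validate = FALSE)),
               geodesic_point(A, B, 0.5), tolerance = 1e-6,
               ignore_attr = TRUE)

  sc <- cov_set(list(diag(c(1, 2)), diag(c(4, 8))))
  expect_equal(geometric_mean(sc), diag(c(2, 4)), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("geometric mean satisfies the Karcher equation and equivariance", {
  set.seed(12)
  s <- rand_spd_set(8, 5)
  G <- geometric_mean(s)
  Gih <- sym_power(G, -0.5)
  L <- Reduce(`+`, Map(function(C, w) {
    M <- Gih %*% C %*% Gih
    w * mfield:::sym_log((M + t(M)) / 2)
  }, s$matrices, s$weights))
  expect_lt(sqrt(sum(L^2)), 1e-6)

  # congruence equivariance G({F C F'}) = F G({C}) F'
  F_ <- matrix(rnorm(25), 5)
  sF <- cov_set(lapply(s$matrices, function(C) {
    M <- F_ %*% C %*% t(F_); (M + t(M)) / 2
  }), validate = FALSE)
  GF <- geometric_mean(sF)
  expect_equal(GF, F_ %*% G %*% t(F_), tolerance = 1e-6,
               ignore_attr = TRUE)

  # uniqueness: result independent of initialization
  G2 <- geometric_mean(s, init = diag(5) * 3)
  expect_lt(airm_distance(G, G2), 1e-6)
})

test_that("power mean: scalar reduction to (sum w c^h)^(1/h) for all h", {
  vals <- c(1, 16)
  s <- cov_set(lapply(vals, function(v) matrix(v, 1, 1)))
  expect_equal(power_mean(s, 0.5, tol = 1e-13)[1, 1], 6.25,
               tolerance = 1e-10)
  for (h in setdiff(default_h_field(), 0)) {
    expect_equal(power_mean(s, h, tol = 1e-13)[1, 1], mean(vals^h)^(1 / h),
                 tolerance = 1e-10, label = sprintf("h = %g", h))
  }
  expect_equal(power_mean(s, 0, tol = 1e-12)[1, 1], sqrt(16 * 1),
               tolerance = 1e-10)
})

test_that("power mean endpoints, duality, residual contract", {
  set.seed(13)
  s <- rand_spd_set(10, 5)
  expect_equal(power_mean(s, 1), arithmetic_mean(s), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(power_mean(s, -1), harmonic_mean(s), tolerance = 1e-6,
               ignore_attr = TRUE)

  # duality: P_{-h}(set) = [P_h(set^{-1})]^{-1}
  sinv <- cov_set(lapply(s$matrices, solve), weights = s$weights,
                  validate = FALSE)
  expect_equal(power_mean(s, -0.5), solve(power_mean(sinv, 0.5)),
               tolerance = 1e-7, ignore_attr = TRUE)

  # self-consistency P = sum w_k (P #_h C_k), relative Frobenius residual
  for (h in c(0.25, 0.75, -0.25)) {
    P <- power_mean(s, h)
    R <- Reduce(`+`, Map(function(C, w) w * geodesic_point(P, C, h),
                         s$matrices, s$weights))
    expect_lt(norm(P - R, "F") / norm(P, "F"), 10 * 1e-7)
  }
  expect_error(power_mean(s, 1.5), "\\[-1, 1\\]")
})

test_that("geometric mean is the h -> 0 limit of the power mean", {
  set.seed(14)
  s <- rand_spd_set(10, 6)
  G <- geometric_mean(s)
  span <- airm_distance(harmonic_mean(s), arithmetic_mean(s))
  expect_lt(airm_distance(power_mean(s, 0.01), G), 0.01 * span)
  expect_lt(airm_distance(power_mean(s, -0.01), G), 0.01 * span)
})

test_that("means are invariant to trial permutation", {
  set.seed(15)
  s <- rand_spd_set(7, 4)
  perm <- sample(7)
  sp <- cov_set(s$matrices[perm], weights = s$weights[perm],
                validate = FALSE)
  for (h in c(1, 0.5, 0, -0.5, -1)) {
    expect_equal(power_mean(s, h), power_mean(sp, h), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("compute_means_field: structure, warm-start independence", {
  set.seed(16)
  C <- rand_spd(3)
  s1 <- cov_set(rep(list(C), 5), labels = rep("a", 5), validate = FALSE)
  f1 <- compute_means_field(s1)
  expect_length(f1$means[["a"]], 11)
  for (h in default_h_field())
    expect_equal(field_mean(f1, "a", h), C, tolerance = 1e-6,
                 ignore_attr = TRUE)

  set2 <- make_two_class_set(n_channels = 4, n_trials_per_class = 15,
                             seed = 21)
  f2 <- compute_means_field(set2)
  expect_equal(length(f2$means[[1]]), 11)
  expect_equal(length(f2$means[[2]]), 11)
  expect_equal(f2$classes, c("class1", "class2"))

  # warm-started field equals cold-started (identity init) solves
  for (cl in f2$classes) {
    idx <- which(set2$labels == cl)
    sub <- cov_set(set2$matrices[idx], validate = FALSE)
    for (h in c(0.5, -0.25, 0)) {
      cold <- power_mean(sub, h, init = diag(4))
      expect_lt(airm_distance(cold, field_mean(f2, cl, h)), 1e-5)
    }
  }
})

test_that("standardized geodesic distances", {
  set.seed(17)
  center <- diag(3)
  # equidistant trials -> all-zero z-scores
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  s <- cov_set(list(2 * diag(3), Q %*% (2 * diag(3)) %*% t(Q)),
               validate = FALSE)
  expect_equal(standardized_distances(s, center), c(0, 0))

  # direct arithmetic on distances (1, 1, 1, 5): scale to distance d via cI
  mk <- function(d) exp(d / sqrt(3)) * diag(3)   # airm dist to I = d
  s4 <- cov_set(lapply(c(1, 1, 1, 5), mk), validate = FALSE)
  z <- standardized_distances(s4, center)
  expect_equal(z[4], (5 - 2) / 2, tolerance = 1e-10)
  expect_equal(sum(z), 0, tolerance = 1e-10)
  expect_error(standardized_distances(cov_set(list(diag(3)),
                                              validate = FALSE), center),
               "2 trials")
})

test_that("robust_mean trims planted outliers and respects its caps", {
  set.seed(18)
  clean <- sample_spd_cloud(diag(3), 0.2, 20, seed = 31)
  # no outliers below threshold -> identical to the plain mean
  rm0 <- robust_mean(clean, h = 0)
  if (length(rm0$retained) == 20L)
    expect_equal(rm0$mean, geometric_mean(clean), tolerance = 1e-9,
                 ignore_attr = TRUE)

  # planted gross outlier is removed and the robust mean is closer
  s <- cov_set(c(clean$matrices, list(1e4 * diag(3))), validate = FALSE)
  rm1 <- robust_mean(s, h = 0)
  expect_false(21L %in% rm1$retained)
  expect_lt(airm_distance(rm1$mean, diag(3)),
            airm_distance(geometric_mean(s), diag(3)))

  # a single refinement removes at most one batch
  rm2 <- robust_mean(s, h = 0, max_refinements = 1L)
  expect_gte(length(rm2$retained), length(rm1$retained))

  # min_retained guard: removal that would shrink below it is skipped
  tiny <- cov_set(list(diag(2), diag(2), 100 * diag(2)), validate = FALSE)
  rm3 <- robust_mean(tiny, h = 0, z_threshold = 1, min_retained = 3L)
  expect_equal(rm3$retained, 1:3)
})

test_that("robust_means_field equals the field on the cleaned set", {
  set.seed(19)
  s <- make_two_class_set(n_channels = 3, n_trials_per_class = 20,
                          dispersion = 0.2, class_separation = 1,
                          outlier_fraction = 0.1, outlier_magnitude = 10,
                          seed = 41)
  rf <- robust_means_field(s)
  kept <- sort(unlist(attr(rf, "retained")))
  manual <- compute_means_field(
    cov_set(s$matrices[kept], labels = s$labels[kept], validate = FALSE))
  for (cl in rf$classes) for (h in c(-1, 0, 0.5))
    expect_equal(field_mean(rf, cl, h), field_mean(manual, cl, h),
                 tolerance = 1e-12, ignore_attr = TRUE)

  # retained indices never mix classes
  ret <- attr(rf, "retained")
  expect_true(all(s$labels[ret$class1] == "class1"))
  expect_true(all(s$labels[ret$class2] == "class2"))

  # outlier-free set: field identical to the non-robust one
  s0 <- make_two_class_set(n_channels = 3, n_trials_per_class = 12,
                           dispersion = 0.2, seed = 42)
  rf0 <- robust_means_field(s0)
  if (length(unlist(attr(rf0, "retained"))) == length(s0)) {
    f0 <- compute_means_field(s0)
    for (cl in rf0$classes)
      expect_equal(field_mean(rf0, cl, 0), field_mean(f0, cl, 0),
                   tolerance = 1e-12, ignore_attr = TRUE)
  }
})
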