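# Manifold classifiers: MDM, MDMF, MF and the closed-form linear
# discriminant behind MF.

two_class_fixture <- function(seed = 50, n = 15, disp = 0.3, sep = 1.2,
                              nc = 3) {
  make_two_class_set(n_channels = nc, n_trials_per_class = n,
                     dispersion = disp, class_separation = sep, seed = seed)
}

test_that("MDM: definitional reductions and nearest-mean rule", {
  set.seed(51)
  C1 <- rand_spd(3); C2 <- rand_spd(3)
  s <- cov_set(c(rep(list(C1), 3), rep(list(C2), 3)),
               labels = rep(c("a", "b"), each = 3), validate = FALSE)
  m <- mdm(s)
  expect_equal(field_mean(m$field, "a", 0), C1, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(field_mean(m$field, "b", 0), C2, tolerance = 1e-7,
               ignore_attr = TRUE)

  # equals compute_means_field restricted to h = 0
  f0 <- compute_means_field(s, h_values = 0)
  expect_equal(field_mean(m$field, "a", 0), field_mean(f0, "a", 0),
               ignore_attr = TRUE)

  # trial at the class-a mean: classified a, score > 0 toward... score is
  # d^2(class a) - d^2(class b) < 0 here (class a = first level)
  pr <- predict(m, C1)
  expect_equal(as.character(pr$class), "a")
  expect_lt(pr$score, 0)

  # equidistant trial: tie broken toward the lower-indexed class, score 0
  meq <- mdm(cov_set(list(diag(c(4, 1)), diag(c(1, 4))),
                     labels = c("a", "b")))
  pr2 <- predict(meq, diag(2))
  expect_equal(as.character(pr2$class), "a")
  expect_equal(pr2$score, 0)

  # separable clouds: high training accuracy
  s2 <- two_class_fixture(seed = 52, disp = 0.2)
  pr3 <- predict(mdm(s2), s2)
  expect_gte(mean(pr3$class == s2$labels), 0.95)

  # permutation invariance at fit time
  perm <- sample(length(s2))
  sp <- cov_set(s2$matrices[perm], labels = s2$labels[perm],
                validate = FALSE)
  expect_equal(field_mean(mdm(sp)$field, "class1", 0),
               field_mean(mdm(s2)$field, "class1", 0), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("MDMF reduces to MDM at h = {0} and uses the global min rule", {
  s <- two_class_fixture(seed = 53)
  m0 <- mdmf(s, h_values = 0)
  md <- mdm(s)
  pr0 <- predict(m0, s); prd <- predict(md, s)
  expect_equal(pr0$class, prd$class)
  expect_equal(pr0$score, prd$score)

  # a field where one class's means all coincide with the probe
  C <- rand_spd(3)
  f <- compute_means_field(
    cov_set(c(rep(list(C), 4), replicate(4, rand_spd(3) + 2 * diag(3),
                                         simplify = FALSE)),
            labels = rep(c("near", "far"), each = 4), validate = FALSE),
    h_values = c(-0.5, 0, 0.5))
  mm <- structure(list(field = f, classes = f$classes), class = "mdmf")
  expect_equal(as.character(predict(mm, C)$class), "near")

  # min rule: nearest single mean wins even if the class is farther on
  # average (three means per class, constructed geometry)
  near_probe <- diag(2)
  clsA <- list(diag(c(1.05, 1.05)), 16 * diag(2), 20 * diag(2))
  clsB <- list(1.5 * diag(2), 1.6 * diag(2), 1.7 * diag(2))
  fld <- list(means = list(A = setNames(clsA, hkey(c(-0.5, 0, 0.5))),
                           B = setNames(clsB, hkey(c(-0.5, 0, 0.5)))),
              classes = c("A", "B"), h_values = c(-0.5, 0, 0.5), dim = 2)
  class(fld) <- "means_field"
  mA <- structure(list(field = fld, classes = fld$classes), class = "mdmf")
  prA <- predict(mA, near_probe)
  expect_equal(as.character(prA$class), "A")
  # average distance to class A means is larger than to class B means
  dA <- sapply(clsA, airm_distance, A = near_probe)
  dB <- sapply(clsB, airm_distance, A = near_probe)
  expect_gt(mean(dA), mean(dB))
  expect_lt(min(dA), min(dB))
})

test_that("mf_features: length, zero entry, congruence invariance", {
  s <- two_class_fixture(seed = 54, n = 10)
  f <- compute_means_field(s)
  v <- mf_features(f, s$matrices[[1]])
  expect_length(v, 22)
  expect_true(all(v >= 0))

  v0 <- mf_features(f, field_mean(f, "class1", 0))
  expect_equal(min(v0), 0, tolerance = 1e-12)
  expect_equal(which.min(v0), 6L)   # class-major, h ascending; h = 0 is 6th

  # joint congruence of probe and field leaves features unchanged
  F_ <- matrix(rnorm(9), 3)
  sF <- cov_set(lapply(s$matrices, function(C) {
    M <- F_ %*% C %*% t(F_); (M + t(M)) / 2
  }), labels = s$labels, validate = FALSE)
  fF <- compute_means_field(sF)
  vF <- mf_features(fF, sF$matrices[[1]])
  expect_equal(vF, v, tolerance = 1e-5)
})

test_that("closed-form LDA: boundary, degeneracy ridge, affinity", {
  # 1-D, symmetric classes, equal priors: boundary at 0
  x <- matrix(c(-1.2, -0.8, -1, 0.8, 1.2, 1), ncol = 1)
  y <- rep(c("n", "p"), each = 3)
  fit <- lda_fit(x, y)
  expect_equal(-fit$b / fit$w, 0, tolerance = 1e-10)
  expect_gt(fit$w, 0)

  # duplicated feature columns trigger the ridge path and still fit
  set.seed(55)
  X <- matrix(rnorm(40), 20, 2)
  X <- cbind(X, X[, 1])
  yy <- rep(c("a", "b"), 10)
  fit2 <- lda_fit(X, yy)
  expect_true(fit2$ridged)
  expect_length(fit2$w, 3)

  # scores are affine in the features
  s1 <- mfield:::lda_score(fit2, X)
  s2 <- mfield:::lda_score(fit2, 2 * X)
  s0 <- mfield:::lda_score(fit2, 0 * X)
  expect_equal(s2 - s1, s1 - s0, tolerance = 1e-10)

  expect_error(lda_fit(X, c("a", rep("b", 19))), "at least 2")
})

test_that("LDA direction matches MASS::lda on a well-posed problem", {
  skip_if_not_installed("MASS")
  set.seed(56)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 1.5), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  fit <- lda_fit(X, y)
  m <- MASS::lda(X, grouping = y)
  cosang <- sum(fit$w * m$scaling) /
    sqrt(sum(fit$w^2) * sum(m$scaling^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-8)
})

test_that("MF is deterministic, beats MDM when dispersions differ", {
  s <- make_two_class_set(n_channels = 3, n_trials_per_class = 25,
                          dispersion = c(0.2, 0.6), class_separation = 0.8,
                          seed = 57)
  m1 <- mf(s); m2 <- mf(s)
  p1 <- predict(m1, s); p2 <- predict(m2, s)
  expect_identical(p1, p2)                       # bitwise determinism

  auc_mf <- auc_roc(p1$score, s$labels)
  pm <- predict(mdm(s), s)
  auc_mdm <- auc_roc(pm$score, s$labels)
  expect_gte(auc_mf, auc_mdm)

  # reduction: h = {0} field + min rule equals MDM
  prd <- predict(mdmf(s, h_values = 0), s)
  expect_equal(prd$class, pm$class)
})

test_that("MF score is invariant under joint congruence of all trials", {
  s <- two_class_fixture(seed = 58, n = 10)
  m <- mf(s)
  sc <- predict(m, s)$score
  F_ <- matrix(rnorm(9), 3)
  sF <- cov_set(lapply(s$matrices, function(C) {
    M <- F_ %*% C %*% t(F_); (M + t(M)) / 2
  }), labels = s$labels, validate = FALSE)
  scF <- predict(mf(sF), sF)$score
  expect_equal(scF, sc, tolerance = 1e-5 * max(1, max(abs(sc))))
})

test_that("MF agrees with MDM on symmetric equal-dispersion problems", {
  s <- make_two_class_set(n_channels = 3, n_trials_per_class = 30,
                          dispersion = 0.25, class_separation = 1.5,
                          seed = 59)
  agree <- mean(predict(mf(s), s)$class == predict(mdm(s), s)$class)
  expect_gt(agree, 0.95)
})

test_that("three-class MF fits one-versus-rest and predicts by argmax", {
  set.seed(60)
  centers <- list(diag(3), 2 * diag(3), diag(c(4, 1, 1)))
  mats <- list(); labs <- character(0)
  for (i in 1:3) {
    cl <- sample_spd_cloud(centers[[i]], 0.15, 12, seed = 60 + i)
    mats <- c(mats, cl$matrices)
    labs <- c(labs, rep(paste0("c", i), 12))
  }
  s <- cov_set(mats, labels = labs, validate = FALSE)
  m <- mf(s, h_values = c(-0.5, 0, 0.5))
  pr <- predict(m, s)
  expect_gte(mean(pr$class == s$labels), 0.9)
  expect_equal(levels(pr$class), c("c1", "c2", "c3"))
})
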