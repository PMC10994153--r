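# functional PCA: eigenfunctions, scores, standardization, quantile curves

test_that("eigenfunctions are orthonormal in L2 and variance fractions decompose", {
  set.seed(7)
  C <- matrix(rnorm(40 * 7, 0, 5), 40, 7) + rep(90, each = 40)
  m <- fit_fpca(curveset_from_coef(C))
  b <- m$basis
  X <- t(b$Phi_grid %*% m$ef_coef)     # components x grid
  for (j in 1:3) {
    expect_equal(sum(b$weights * X[j, ]^2), 1, tolerance = 1e-6)
    for (k in seq_len(j - 1)) {
      expect_lt(abs(sum(b$weights * X[j, ] * X[k, ])), 1e-6)
    }
  }
  expect_true(all(diff(m$variance_explained) <= 1e-12))
  expect_true(all(m$variance_explained > 0 & m$variance_explained <= 1))
  expect_equal(sum(m$eigenvalues / sum(m$eigenvalues)), 1, tolerance = 1e-8)
})

test_that("a planted single component is recovered with its variance", {
  set.seed(21)
  bu <- unit_fn(rnorm(7))
  mean_coef <- rep(95, 7)
  a <- rnorm(200)
  C <- matrix(mean_coef, 200, 7, byrow = TRUE) + outer(a, bu)
  m <- fit_fpca(curveset_from_coef(C))
  xi1 <- drop(default_basis$Phi_grid %*% m$ef_coef[, 1])
  u <- drop(default_basis$Phi_grid %*% bu)
  expect_gte(abs(fn_cosine(xi1, u)), 0.999)
  expect_gte(m$variance_explained[1], 0.999)
  expect_equal(m$eigenvalues[1], var(a), tolerance = 1e-8)
})

test_that("vertical-shift variation yields the constant eigenfunction 1/sqrt(120)", {
  set.seed(5)
  base <- rnorm(7, 90, 10)
  shifts <- rnorm(50, 0, 8)
  C <- matrix(base, 50, 7, byrow = TRUE) + outer(shifts, rep(1, 7))
  m <- fit_fpca(curveset_from_coef(C))
  xi1 <- drop(default_basis$Phi_grid %*% m$ef_coef[, 1])
  expect_true(all(abs(xi1 - 1 / sqrt(120)) < 1e-8))
})

test_that("degenerate and undersized cohorts are rejected", {
  C <- matrix(rep(c(90, 95, 100, 98, 96, 92, 90), each = 10), 10, 7)
  expect_error(fit_fpca(curveset_from_coef(C)), "degenerate|identical")
  expect_error(fit_fpca(curveset_from_coef(C[1:3, ] + rnorm(21))),
               "at least 4 curves")
})

test_that("scores center at the mean, pick out planted components, and decorrelate", {
  set.seed(9)
  C <- matrix(rnorm(60 * 7, 0, 4), 60, 7) + rep(c(85, 100, 120, 115, 105, 95, 90), each = 60)
  cs <- curveset_from_coef(C)
  m <- fit_fpca(cs)
  # the cohort mean curve scores 0 on every component
  z0 <- fpc_scores(m, curveset_from_coef(matrix(m$mean_coef, 1)))
  expect_true(all(abs(z0) < 1e-8))
  # mean + 2.5 * xi_1 scores (2.5, 0, 0)
  z1 <- fpc_scores(m, curveset_from_coef(matrix(m$mean_coef + 2.5 * m$ef_coef[, 1], 1)))
  expect_equal(drop(z1), c(z1 = 2.5, z2 = 0, z3 = 0), tolerance = 1e-8)
  # training scores have diagonal covariance with the eigenvalues
  Z <- fpc_scores(m, cs)
  V <- cov(Z)
  expect_equal(diag(V), m$eigenvalues[1:3], tolerance = 1e-6,
               ignore_attr = TRUE)
  off <- V[upper.tri(V)]
  expect_true(all(abs(off) < 1e-6 * max(diag(V))))
})

test_that("score computation checks analyte and basis compatibility", {
  set.seed(1)
  C <- matrix(rnorm(40 * 7, 0, 5), 40, 7) + 90
  m <- fit_fpca(curveset_from_coef(C, analyte = "glucose"))
  expect_error(fpc_scores(m, curveset_from_coef(C, analyte = "insulin")),
               "analyte mismatch")
})

test_that("standardized scores have exact mean 0 / sd 1 and match the 2-point closed form", {
  set.seed(13)
  Z <- matrix(rnorm(30 * 3, 5, 2), 30, 3, dimnames = list(NULL, c("z1", "z2", "z3")))
  Zs <- standardize_scores(Z)
  expect_true(all(abs(colMeans(Zs)) < 1e-10))
  expect_true(all(abs(apply(Zs, 2, sd) - 1) < 1e-10))
  two <- standardize_scores(matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "z1")))
  expect_equal(drop(two), c(-1, 1) / sqrt(2), tolerance = 1e-7)
  expect_error(standardize_scores(matrix(1, 5, 1)), "zero-variance")
})

test_that("functional route matches the grid-discretized eigendecomposition oracle", {
  set.seed(33)
  for (r in 1:10) {
    n <- sample(20:60, 1)
    A <- matrix(rnorm(49, 0, 2), 7, 7)
    C <- matrix(rnorm(n * 7), n, 7) %*% A + rep(rnorm(7, 95, 10), each = n)
    m <- fit_fpca(curveset_from_coef(C))
    orc <- fpca_grid_oracle(C)
    expect_equal(m$eigenvalues[1:3], orc$values[1:3], tolerance = 1e-4)
    for (k in 1:3) {
      xi <- drop(default_basis$Phi_grid %*% m$ef_coef[, k])
      expect_gte(abs(fn_cosine(xi, orc$xi[, k])), 0.999)
    }
  }
})

test_that("three planted components at eigenvalue ratio 10:3:1 are recovered", {
  set.seed(77)
  B <- matrix(rnorm(21), 7, 3)
  # Gram-Schmidt under the L2 inner product
  B[, 1] <- unit_fn(B[, 1])
  for (k in 2:3) {
    for (j in seq_len(k - 1)) {
      B[, k] <- B[, k] - drop(t(B[, j]) %*% default_basis$J %*% B[, k]) * B[, j]
    }
    B[, k] <- unit_fn(B[, k])
  }
  n <- 500
  scores <- cbind(rnorm(n, 0, sqrt(10)), rnorm(n, 0, sqrt(3)), rnorm(n, 0, 1))
  C <- matrix(rep(95, 7), n, 7, byrow = TRUE) + scores %*% t(B) +
    matrix(rnorm(n * 7, 0, 0.02), n, 7)
  m <- fit_fpca(curveset_from_coef(C))
  for (k in 1:3) {
    xi <- drop(default_basis$Phi_grid %*% m$ef_coef[, k])
    planted <- drop(default_basis$Phi_grid %*% B[, k])
    expect_gte(abs(fn_cosine(xi, planted)), 0.95)
  }
  expect_equal(m$eigenvalues[1:3], c(10, 3, 1), tolerance = 0.25)
})

test_that("eigenfunction signs follow the nonnegative-integral convention", {
  set.seed(3)
  C <- matrix(rnorm(50 * 7, 0, 5), 50, 7) + 90
  m <- fit_fpca(curveset_from_coef(C))
  for (k in 1:3) {
    xi <- drop(default_basis$Phi_grid %*% m$ef_coef[, k])
    s <- sum(default_basis$weights * xi)
    expect_true(s >= 0 || (abs(s) < 1e-9 && xi[1] > 0))
  }
})

test_that("quartile and decile mean-curve summaries bin as specified", {
  set.seed(15)
  bu <- unit_fn(rep(1, 7))
  a <- seq(-7, 7, length.out = 8)
  C <- matrix(rep(95, 7), 8, 7, byrow = TRUE) + outer(a, drop(bu)) +
    matrix(rnorm(56, 0, 0.01), 8, 7)
  cs <- curveset_from_coef(C)
  m <- fit_fpca(cs)
  Z <- fpc_scores(m, cs)
  qc <- quartile_curves(m, Z, cs)
  expect_equal(length(unique(qc$bin[qc$component == "z1"])), 4L)
  # 8 participants -> 4 bins of 2 per component
  expect_true(all(table(findInterval(Z[, 1], quantile(Z[, 1], c(.25, .5, .75)),
                                     left.open = TRUE)) == 2))
  # FPC1 here is curve level: quartile means are pointwise ordered
  w <- qc[qc$component == "z1", ]
  q_mat <- sapply(split(w$value, w$bin), identity)[, paste0("Q", 1:4)]
  frac_ordered <- mean(q_mat[, 1] <= q_mat[, 2] & q_mat[, 2] <= q_mat[, 3] &
                         q_mat[, 3] <= q_mat[, 4])
  expect_gte(frac_ordered, 0.9)
  dc <- quartile_curves(m, Z, cs, type = "decile")
  expect_setequal(unique(dc$bin), c("bottom 10%", "top 10%"))
})
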