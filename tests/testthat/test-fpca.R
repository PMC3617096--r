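# FPCA core: centering, covariance estimation, smoothing, noise
# variance, eigendecomposition, scores and reconstruction.

test_that("centering subtracts per-gene means and respects the missing mask", {
  df <- wide_tibble(matrix(c(5, 5, 5, 5,
                             1, 2, 3, 2,
                             1, NA, 3, 2), 3, 4, byrow = TRUE), c(0, 1, 2, 3))
  cen <- center_by_gene_mean(df)
  expect_equal(cen$gene_means, c(5, 2, 2), ignore_attr = TRUE)
  expect_equal(cen$centered[1, ], c(0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(cen$centered[2, ], c(-1, 0, 1, 0), ignore_attr = TRUE)
  expect_equal(cen$centered[3, c(1, 3, 4)], c(-1, 1, 0), ignore_attr = TRUE)
  # idempotence: centering already-centered data changes nothing
  df2 <- wide_tibble(ifelse(is.na(cen$centered), NA, cen$centered), c(0, 1, 2, 3))
  cen2 <- center_by_gene_mean(df2)
  expect_equal(cen2$centered, cen$centered, ignore_attr = TRUE)
  expect_equal(cen2$gene_means, rep(0, 3), ignore_attr = TRUE)
})

test_that("raw covariance matches closed forms on degenerate inputs", {
  # identical centered profiles: C = c c^T
  cvec <- c(-1, 0.5, 0.5)
  df <- wide_tibble(matrix(cvec, 4, 3, byrow = TRUE) + 7, c(0, 1, 2))
  C <- raw_covariance(center_by_gene_mean(df))
  expect_equal(C, tcrossprod(cvec), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("raw covariance converges to the generating covariance (Monte Carlo)", {
  sim <- simulate_one_group(5000, pi0 = 1, seed = 7)
  em <- fpcatest:::as_expr_mat(sim$data)
  C <- raw_covariance(center_by_gene_mean(em))
  phi <- basis_one_group(em$times)
  G <- phi %*% diag(c(4, 2, 1)) %*% t(phi)
  off <- row(C) != col(C)
  expect_lt(max(abs(C - G)[off]), 0.15)
  # diagonal ridge is approximately sigma^2 = 0.01 above the smooth surface
  ridge <- mean(diag(C) - diag(G))
  expect_gt(ridge, 0.003)
  expect_lt(ridge, 0.02)
})

test_that("surface smoother is exact on bilinear surfaces and preserves symmetry", {
  g <- seq(0, 1, length.out = 10)
  raw <- outer(g, g)
  sm <- smooth_covariance(raw, g, bandwidth = 0.3)
  expect_lt(max(abs(sm$smooth - outer(g, g))), 1e-6)
  expect_identical(sm$smooth, t(sm$smooth))
})

test_that("smoothing removes the diagonal noise ridge of a rank-1 surface", {
  g <- seq(100, 305, length.out = 51)
  phi <- basis_one_group(g)[, 1]
  raw <- 4 * tcrossprod(phi) + diag(0.01, length(g))
  sm <- smooth_covariance(raw, g, bandwidth = "gcv")
  expect_lt(max(abs(diag(sm$smooth) - 4 * phi^2)), 0.05)
})

test_that("noise variance estimator recovers sigma^2 and clips at zero", {
  g <- seq(100, 305, length.out = 21)
  phi <- basis_one_group(g)[, 1]
  smooth_only <- 4 * tcrossprod(phi)
  # a ridge-free surface may give a tiny negative estimate, clipped to 0
  expect_lt(suppressWarnings(estimate_noise_variance(smooth_only, g)), 1e-3)
  # negative ridge is clipped at zero with a warning
  expect_warning(
    s2 <- estimate_noise_variance(smooth_only - diag(0.02, 21), g),
    "clipped"
  )
  expect_identical(s2, 0)
  # recovery of the generating noise variance from simulated data
  sim <- simulate_one_group(5000, pi0 = 1, seed = 11)
  C <- raw_covariance(center_by_gene_mean(sim$data))
  s2 <- estimate_noise_variance(C, fpcatest:::as_expr_mat(sim$data)$times)
  expect_gt(s2, 0.007)
  expect_lt(s2, 0.013)
})

test_that("eigendecomposition recovers a rank-1 surface and keeps quadrature orthonormality", {
  tt <- seq(100, 305, length.out = 21)
  phi <- basis_one_group(tt)[, 1]
  eig <- eigendecompose(4 * tcrossprod(phi), tt)
  expect_lt(abs(eig$eigenvalues[1] - 4) / 4, 0.02)
  w <- fpcatest:::trapezoid_weights(tt)
  expect_lt(abs(abs(sum(w * eig$eigenfunctions[, 1] * phi)) - 1), 1e-3)
  # orthonormality contract for a multi-component surface
  phi3 <- basis_one_group(tt)
  eig3 <- eigendecompose(phi3 %*% diag(c(4, 2, 1)) %*% t(phi3), tt)
  L <- 3
  gram <- t(eig3$eigenfunctions[, 1:L]) %*% (w * eig3$eigenfunctions[, 1:L])
  expect_lt(max(abs(gram - diag(L))), 1e-6)
  expect_equal(eig3$fve[1:3], c(4, 6, 7) / 7, tolerance = 1e-3)
  # a surface with no positive component is rejected
  expect_error(eigendecompose(-diag(21) * 0.1, tt), "no positive component")
})

test_that("eigendecomposition agrees with the dense weighted eigensolver oracle", {
  set.seed(3)
  g <- sort(runif(6))
  A <- matrix(rnorm(36), 6)
  G <- crossprod(A) / 6
  eig <- eigendecompose(G, g)
  w <- fpcatest:::trapezoid_weights(g)
  oracle <- eigen(diag(sqrt(w)) %*% G %*% diag(sqrt(w)), symmetric = TRUE)$values
  expect_equal(eig$eigenvalues, oracle[oracle > 0], tolerance = 1e-8)
})

test_that("component selection follows the cumulative FVE rule", {
  expect_identical(select_components(c(4, 2, 1), threshold = 0.90), 3L)
  expect_identical(select_components(c(4, 2, 1), threshold = 0.50), 1L)
  expect_identical(select_components(c(1, 0, 0)[1], threshold = 0.99), 1L)
  expect_error(select_components(numeric(0)), "positive eigenvalue")
})

test_that("integral scores recover known coefficients on a dense grid", {
  tt <- seq(100, 305, length.out = 101)
  phi <- basis_one_group(tt)
  eig <- manual_eig(phi, tt)
  z1 <- matrix(2 * phi[, 1], 1)
  s <- estimate_scores(z1, eig)
  expect_lt(abs(s[1] - 2) / 2, 0.01)
  expect_lt(max(abs(s[2:3])), 0.02)
  expect_equal(estimate_scores(matrix(0, 1, 101), eig), matrix(0, 1, 3),
               ignore_attr = TRUE)
  s2 <- estimate_scores(matrix(2 * phi[, 1] - 3 * phi[, 2], 1), eig)
  expect_equal(as.numeric(s2[1:2]), c(2, -3), tolerance = 0.01)
})

test_that("reconstruction is self-consistent and LS projection is an upper-bound oracle", {
  tt <- seq(100, 305, length.out = 51)
  phi <- basis_one_group(tt)
  eig <- manual_eig(phi, tt)
  # zero scores reproduce the constant gene mean and the null RSS
  df <- wide_tibble(matrix(rnorm(2 * 51), 2) + 5, tt)
  cen <- center_by_gene_mean(df)
  rec0 <- reconstruct(cen$gene_means, matrix(0, 2, 3), eig, data = df)
  expect_true(all(rec0$fitted == cen$gene_means))
  expect_equal(rec0$rss, rowSums(cen$centered^2), ignore_attr = TRUE)
  # noiseless gene mu + 2 phi_1 reconstructed with negligible RSS
  y <- 3 + 2 * phi[, 1]
  dfy <- wide_tibble(matrix(y, 1), tt)
  ceny <- center_by_gene_mean(dfy)
  s <- estimate_scores(ceny, eig)
  rec <- reconstruct(ceny$gene_means, s, eig, data = dfy)
  expect_lt(rec$rss, 1e-3 * length(tt))
  # least-squares projection onto {1, phi} never exceeds the null RSS
  yn <- y + rnorm(51, sd = 0.1)
  fitls <- lm.fit(cbind(1, phi), yn)
  expect_lte(sum(fitls$residuals^2), sum((yn - mean(yn))^2) + 1e-8)
})

test_that("fpca recovers generating eigenvalues, noise and component count", {
  sim <- simulate_one_group(1000, pi0 = 1, seed = 5)
  fit <- fpca(sim$data)
  expect_identical(fit$L, 3L)
  expect_lt(max(abs(fit$eig$eigenvalues[1:3] - c(4, 2, 1)) / c(4, 2, 1)), 0.25)
  expect_gt(fit$sigma2, 0.005)
  expect_lt(fit$sigma2, 0.02)
  tt <- tidy(fit)
  expect_named(tt, c("gene", "mean", "rss0", "rss1", "score_1", "score_2", "score_3"))
  expect_true(all(tt$rss1 >= 0))
})

test_that("masking 5% of entries perturbs eigenvalues by less than 10%", {
  sim <- simulate_one_group(1000, pi0 = 1, seed = 9)
  fit_full <- fpca(sim$data)
  df <- sim$data
  m <- as.matrix(df[-1])
  set.seed(21)
  idx <- sample(length(m), round(0.05 * length(m)))
  m[idx] <- NA
  dfm <- wide_tibble(m, fpcatest:::as_expr_mat(sim$data)$times, df$gene)
  fit_m <- fpca(dfm)
  rel <- abs(fit_m$eig$eigenvalues[1:3] - fit_full$eig$eigenvalues[1:3]) /
    fit_full$eig$eigenvalues[1:3]
  expect_lt(max(rel), 0.10)
})
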