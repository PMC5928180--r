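test_that("truncated SVD handles the diagonal case and full rank exactly", {
  fit <- svd_truncated(diag(c(3, 1)), 1)
  expect_equal(fit$d, 3)
  expect_equal(reconstruct(fit), matrix(c(3, 0, 0, 0), 2), tolerance = 1e-12)
  X <- rank_k_matrix(6, 5, 3, seed = 10)
  full <- svd_truncated(X, 3)
  expect_lt(sqrt(sum((X - reconstruct(full))^2)), 1e-10)
})

test_that("rank-k SVD error matches the Eckart-Young eigen-oracle", {
  set.seed(11)
  X <- matrix(rnorm(30), 6, 5)
  fit <- svd_truncated(X, 2)
  err <- sum((X - reconstruct(fit))^2)
  # oracle: tail eigenvalues of X^T X from a dense eigen-decomposition
  ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(err, sum(ev[-(1:2)]), tolerance = 1e-10)
  expect_equal(crossprod(fit$U), diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(tcrossprod(fit$V), diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(fit$d) <= 0))
  expect_error(svd_truncated(X, 9), "k must lie")
})

test_that("PCA equals the covariance eigen-oracle up to sign", {
  X <- matrix(rep(runif(6), 8), 6, 8)  # identical columns
  expect_lt(max(abs(pca_unmix(X, 2)$d)), 1e-12)
  # 2-d point cloud along y = x
  set.seed(12)
  t <- rnorm(200)
  cloud <- rbind(t, t) + matrix(rnorm(400, sd = 0.01), 2)
  p1 <- pca_unmix(cloud, 1)
  expect_equal(abs(p1$U[, 1]), c(1, 1) / sqrt(2), tolerance = 0.02)
  # general case against eigen() on the covariance of centered data
  A <- matrix(rnorm(10 * 40), 10, 40)
  k <- 3
  fit <- pca_unmix(A, k)
  Xc <- mean_center(A)$Xc
  eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
  for (j in seq_len(k)) {
    v <- eg$vectors[, j]
    expect_equal(abs(sum(v * fit$U[, j])), 1, tolerance = 1e-8)
    expect_equal(fit$d[j]^2, eg$values[j], tolerance = 1e-8)
  }
  # sign convention: largest-magnitude loading is positive
  for (j in seq_len(k)) expect_gt(fit$U[which.max(abs(fit$U[, j])), j], 0)
  expect_equal(sum(pca_unmix(A, 10)$explained_variance), 1, tolerance = 1e-8)
})

test_that("PCA reconstruction at full rank reproduces the data", {
  set.seed(13)
  A <- matrix(runif(8 * 12), 8, 12)
  fit <- pca_unmix(A, 8)
  expect_equal(reconstruct(fit), A, tolerance = 1e-8)
})

test_that("NMF recovers exactly representable low-rank data", {
  set.seed(14)
  u <- runif(10, 0.1, 1); v <- runif(15, 0.1, 1)
  X <- outer(u, v)
  fit <- nmf_unmix(X, unmixing_config(k = 1, seed = 1, tol = 1e-12,
                                      max_iter = 2000))
  expect_lt(sqrt(sum((X - reconstruct(fit))^2)) / sqrt(sum(X^2)), 1e-6)
  # zero matrix factorizes to zero with objective 0
  z <- nmf_unmix(matrix(0, 4, 6), unmixing_config(k = 2, seed = 1))
  expect_equal(max(reconstruct(z)), 0, tolerance = 1e-20)
  expect_equal(final_objective(z), 0)
  expect_error(nmf_unmix(matrix(c(-1, 1), 1), unmixing_config(k = 1)),
               "non-negative")
})

test_that("multiplicative traces are non-increasing and factors stay non-negative", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(runif(20 * 30), 20, 30)
    for (loss in c("frobenius", "kl")) {
      fit <- nmf_unmix(X, unmixing_config(k = 3, loss = loss, seed = seed,
                                          max_iter = 80))
      expect_monotone_trace(fit)
      expect_true(all(fit$U >= 0) && all(fit$V >= 0))
    }
  }
})

test_that("solver is reproducible for a fixed seed and config", {
  set.seed(15)
  X <- matrix(runif(12 * 20), 12, 20)
  cfg <- unmixing_config(k = 3, seed = 99, max_iter = 50)
  a <- nmf_unmix(X, cfg); b <- nmf_unmix(X, cfg)
  expect_identical(a$U, b$U)
  expect_identical(a$V, b$V)
  expect_identical(a$objective_trace, b$objective_trace)
})

test_that("exit normalization leaves reconstruction and loss invariant", {
  set.seed(16)
  X <- matrix(runif(15 * 25), 15, 25)
  cfg <- unmixing_config(k = 3, seed = 2, max_iter = 60)
  fit <- nmf_unmix(X, cfg)
  expect_equal(sqrt(colSums(fit$U^2)), rep(1, 3), tolerance = 1e-12)
  # the recorded final objective was computed pre-normalization; recomputing
  # on the normalized factors gives the same reconstruction loss
  expect_equal(unmix_objective(X, fit$U, fit$V, cfg), final_objective(fit),
               tolerance = 1e-10)
})

test_that("L1 penalty off reproduces plain NMF; sweep drives V sparse", {
  truth <- small_truth(seed = 3)
  X <- cube_to_matrix(make_cube(truth))$X
  base <- nmf_unmix(X, unmixing_config(k = 3, seed = 3, max_iter = 150))
  sp0 <- nmf_unmix(X, unmixing_config(k = 3, seed = 3, lambda1 = 0,
                                      max_iter = 150))
  expect_identical(base$objective_trace, sp0$objective_trace)
  expect_identical(base$V, sp0$V)
  zeros <- sapply(c(0, 0.01, 0.1, 1), function(l1) {
    f <- nmf_unmix(X, unmixing_config(k = 3, seed = 3, lambda1 = l1,
                                      max_iter = 150))
    sum(f$V < 1e-3)
  })
  expect_true(all(diff(zeros) >= 0))
  expect_monotone_trace(
    nmf_unmix(X, unmixing_config(k = 3, seed = 3, lambda1 = 0.1,
                                 max_iter = 150)))
  expect_error(unmixing_config(k = 3, lambda1 = -1), "lambda1")
})

test_that("the worked four-endmember pixel has exactly two insignificant entries", {
  v <- read.csv(system.file("extdata", "worked_abundance.csv",
                            package = "unmixr"))$abundance
  expect_equal(v[3], 0.015)
  expect_equal(count_insignificant(v, floor = 0.05), 2)
})

test_that("spatial regularization reduces edge roughness on salt-and-pepper fields", {
  truth <- make_ground_truth(k = 3, m = 60, grid_shape = c(12, 12), seed = 4,
                             sparsity = 0.6, smoothness_scale = 2)
  dm <- cube_to_matrix(make_cube(truth))
  g <- build_grid_adjacency(dm$grid_shape, 4)
  f0 <- nmf_unmix(dm, unmixing_config(k = 3, seed = 4, max_iter = 200))
  fg <- nmf_unmix(dm, unmixing_config(k = 3, seed = 4, lambda2 = 0.1,
                                      max_iter = 200), graph = g)
  expect_lt(edge_roughness(fg$V, g), edge_roughness(f0$V, g))
  expect_monotone_trace(fg)
  # lambda2 = 0 follows the unregularized trajectory exactly
  fz <- nmf_unmix(dm, unmixing_config(k = 3, seed = 4, lambda2 = 0,
                                      max_iter = 200), graph = g)
  expect_identical(fz$V, f0$V)
  expect_error(nmf_unmix(dm, unmixing_config(k = 3, lambda2 = 0.1)), "graph")
  expect_error(nmf_unmix(dm, unmixing_config(k = 3, seed = 1, lambda2 = 0.1),
                         graph = build_grid_adjacency(c(2, 2), 4)), "pixels")
})

test_that("two identical pixels joined by an edge get equal abundances", {
  set.seed(17)
  spec <- runif(20, 0.1, 1)
  X <- cbind(spec, spec)
  g <- spatial_graph(matrix(c(0, 1, 1, 0), 2))
  fit <- nmf_unmix(X, unmixing_config(k = 2, seed = 1, lambda2 = 0.5,
                                      max_iter = 500), graph = g)
  expect_equal(fit$V[, 1], fit$V[, 2], tolerance = 1e-6)
})

test_that("literal co-activation penalty is exposed and enters the objective", {
  set.seed(18)
  X <- matrix(runif(10 * 9), 10, 9)
  g <- build_grid_adjacency(c(3, 3), 4)
  cfg <- unmixing_config(k = 2, seed = 1, lambda2 = 0.05,
                         literal_penalty = TRUE, max_iter = 50)
  fit <- nmf_unmix(X, cfg, graph = g)
  M <- fit$V %*% as.matrix(g$W) %*% t(fit$V)
  manual <- sum((X - reconstruct(fit))^2) + 0.05 * sum(M^2)
  expect_equal(unmix_objective(X, fit$U, fit$V, cfg, g), manual,
               tolerance = 1e-10)
})

test_that("sum-to-one puts every abundance column on the simplex", {
  # k = 1 forces the all-ones abundance row
  set.seed(19)
  X <- matrix(runif(8 * 10, 0.1, 1), 8, 10)
  f1 <- nmf_unmix(X, unmixing_config(k = 1, seed = 1, sum_to_one = TRUE))
  expect_equal(as.vector(f1$V), rep(1, 10), tolerance = 1e-12)
  for (loss in c("frobenius", "kl")) {
    fit <- nmf_unmix(X, unmixing_config(k = 3, seed = 1, sum_to_one = TRUE,
                                        loss = loss, max_iter = 200))
    expect_lt(max(abs(colSums(fit$V) - 1)), 1e-9)
    expect_true(all(fit$V >= 0))
  }
  # all-zero pixel: abundance set to uniform 1/k with a recorded warning
  Xz <- X; Xz[, 4] <- 0
  fz <- nmf_unmix(Xz, unmixing_config(k = 3, seed = 1, sum_to_one = TRUE,
                                      max_iter = 50))
  expect_equal(fz$V[, 4], rep(1 / 3, 3), tolerance = 1e-12)
  expect_true(any(grepl("uniform 1/k", fz$warnings)))
})

test_that("simplex-generated cubes are recovered on the simplex", {
  truth <- make_ground_truth(seed = 6)  # generator default: simplex abundances
  dm <- cube_to_matrix(make_cube(truth))
  fit <- nmf_unmix(dm, unmixing_config(k = 3, seed = 6, sum_to_one = TRUE,
                                       max_iter = 400))
  expect_lt(max(abs(colSums(fit$V) - 1)), 1e-9)
  rep <- recovery_report(fit, truth)
  expect_lt(rep$abundance_rmse, 0.05)
})

test_that("objective matches a brute-force element-wise oracle", {
  set.seed(20)
  X <- matrix(runif(6 * 8), 6, 8)
  U <- matrix(runif(6 * 2), 6, 2)
  V <- matrix(runif(2 * 8), 2, 8)
  g <- build_grid_adjacency(c(2, 4), 4)
  cfg <- unmixing_config(k = 2, lambda1 = 0.3, lambda2 = 0.2)
  R <- U %*% V
  brute <- 0
  for (i in 1:6) for (j in 1:8) brute <- brute + (X[i, j] - R[i, j])^2
  brute <- brute + 0.3 * sum(abs(V))
  W <- as.matrix(g$W)
  for (a in 1:8) for (b in 1:8)
    brute <- brute + 0.2 * 0.5 * W[a, b] * sum((V[, a] - V[, b])^2)
  expect_equal(unmix_objective(X, U, V, cfg, g), brute, tolerance = 1e-10)
  # UV = X with no penalties gives 0; X = 0 gives the squared Frobenius norm
  expect_equal(unmix_objective(R, U, V, unmixing_config(k = 2)), 0)
  expect_equal(unmix_objective(matrix(0, 6, 8), U, V, unmixing_config(k = 2)),
               sum(R^2))
  # KL against the summation oracle (0 log 0 = 0)
  cfgkl <- unmixing_config(k = 2, loss = "kl")
  Xk <- X; Xk[1, 1] <- 0
  bk <- 0
  for (i in 1:6) for (j in 1:8) {
    x <- Xk[i, j]; r <- R[i, j]
    bk <- bk + (if (x > 0) x * log(x / r) else 0) - x + r
  }
  expect_equal(unmix_objective(Xk, U, V, cfgkl), bk, tolerance = 1e-10)
})

test_that("residual map equals the brute-force column-norm loop", {
  truth <- small_truth(seed = 7)
  dm <- cube_to_matrix(make_cube(truth))
  fit <- nmf_unmix(dm, unmixing_config(k = 3, seed = 7, max_iter = 100))
  res <- residual_map(fit, dm)
  expect_equal(dim(res), c(12L, 12L))
  R <- reconstruct(fit)
  for (j in c(1, 20, 144)) {
    y <- (j - 1) %/% 12 + 1; x <- (j - 1) %% 12 + 1
    brute <- sqrt(sum((dm$X[, j] - R[, j])^2)) /
      (sqrt(sum(dm$X[, j]^2)) + fit$config$eps)
    expect_equal(res[y, x], brute, tolerance = 1e-12)
  }
  # exact-rank data leaves a near-zero residual map
  Xr <- rank_k_matrix(10, 12, 2, seed = 8)
  dmr <- data_matrix(Xr, grid_shape = c(3, 4))
  fr <- nmf_unmix(dmr, unmixing_config(k = 2, seed = 8, tol = 1e-13,
                                       max_iter = 5000))
  expect_lt(max(residual_map(fr, dmr)), 1e-4)
})

test_that("HALS matches multiplicative NMF quality on easy data", {
  X <- rank_k_matrix(12, 18, 2, seed = 9)
  h <- nmf_unmix(X, unmixing_config(k = 2, solver = "hals", seed = 9,
                                    tol = 1e-12, max_iter = 500))
  expect_lt(sqrt(sum((X - reconstruct(h))^2)) / sqrt(sum(X^2)), 1e-6)
  expect_true(all(h$U >= 0) && all(h$V >= 0))
  expect_error(unmixing_config(k = 2, solver = "hals", loss = "kl"),
               "frobenius")
  expect_error(unmixing_config(k = 2, solver = "hals", sum_to_one = TRUE),
               "multiplicative")
})

test_that("nndsvd initialization is deterministic and competitive", {
  X <- rank_k_matrix(15, 20, 3, seed = 10)
  cfg <- unmixing_config(k = 3, init = "nndsvd", max_iter = 1000, tol = 1e-12)
  a <- nmf_unmix(X, cfg); b <- nmf_unmix(X, cfg)
  expect_identical(a$V, b$V)
  expect_lt(sqrt(sum((X - reconstruct(a))^2)) / sqrt(sum(X^2)), 0.05)
})
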