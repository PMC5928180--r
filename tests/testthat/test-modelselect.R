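test_that("dispersion hits its closed-form extremes", {
  # identical labelings across runs: consensus entries all 0/1, rho = 1
  labels <- matrix(rep(c(1L, 1L, 2L, 2L), 4), nrow = 4, byrow = TRUE)
  expect_equal(consensus_dispersion(labels), 1)
  # consensus of exactly 1/2 everywhere off-diagonal
  Cbar <- matrix(0.5, 4, 4)
  expect_equal(dispersion_of_consensus(Cbar), 0)
})

test_that("dispersion of toy consensus matrices equals hand arithmetic", {
  # three hand-written 4x4 connectivity matrices
  C1 <- outer(c(1, 1, 2, 2), c(1, 1, 2, 2), "==") * 1
  C2 <- outer(c(1, 2, 2, 2), c(1, 2, 2, 2), "==") * 1
  C3 <- outer(c(1, 1, 1, 2), c(1, 1, 1, 2), "==") * 1
  Cbar <- (C1 + C2 + C3) / 3
  # hand-tallied consensus entries: 1 on the 4 diagonal cells; pairs (1,2),
  # (2,3), (3,4) agree in 2 of 3 runs (6 cells of 2/3); (1,3), (2,4) in 1 of 3
  # (4 cells of 1/3); (1,4) never (2 cells of 0)
  hand <- (4 * 4 * 0.5^2 + 6 * 4 * (2 / 3 - 0.5)^2 +
             4 * 4 * (1 / 3 - 0.5)^2 + 2 * 4 * 0.5^2) / 16
  expect_equal(dispersion_of_consensus(Cbar), hand, tolerance = 1e-12)
  labels <- rbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 2L, 2L), c(1L, 1L, 1L, 2L))
  expect_equal(consensus_dispersion(labels), hand, tolerance = 1e-12)
})

test_that("dispersion is invariant to relabeling endmember indices", {
  set.seed(21)
  labels <- matrix(sample(1:3, 5 * 12, replace = TRUE), 5, 12)
  rho <- consensus_dispersion(labels)
  perm <- rbind(c(2L, 3L, 1L), c(3L, 1L, 2L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(3L, 2L, 1L))
  relabeled <- labels
  for (r in 1:5) relabeled[r, ] <- perm[r, labels[r, ]]
  expect_equal(consensus_dispersion(relabeled), rho)
})

test_that("dominant endmember breaks ties toward the lowest index", {
  V <- cbind(c(0.5, 0.5, 0), c(0.2, 0.7, 0.1), c(0.3, 0.3, 0.3))
  expect_equal(dominant_endmember(V), c(1L, 2L, 1L))
})

test_that("dispersion over restarts is stable on unambiguous clusters", {
  # two far-apart pure spectra: every restart must assign the same dominant
  # endmember to each pixel, so the consensus is crisp and rho = 1
  set.seed(1)
  u1 <- c(rep(1, 10), rep(0.05, 10)); u2 <- rev(u1)
  X <- cbind(matrix(rep(u1, 8), 20), matrix(rep(u2, 8), 20)) +
    matrix(runif(320, 0, 0.01), 20)
  rho <- dispersion_coefficient(X, 2, n_restarts = 6, seed = 3,
                                config = unmixing_config(k = 2, max_iter = 200))
  expect_equal(rho, 1)
  # on a mixed synthetic cube the statistic stays inside [0, 1]
  truth <- small_truth(seed = 8)
  dm <- cube_to_matrix(make_cube(truth))
  rho3 <- dispersion_coefficient(dm, 3, n_restarts = 4, seed = 1,
                                 config = unmixing_config(k = 3, max_iter = 150))
  expect_gte(rho3, 0)
  expect_lte(rho3, 1)
  expect_error(dispersion_coefficient(dm, 3, n_restarts = 1), "n_restarts")
  expect_error(dispersion_coefficient(matrix(1, 2, 2), 2), "smaller")
})

test_that("elbow selection matches hand-computed second differences", {
  # curvatures: k=2 -> 100-2*10+9 = 89; k=3 -> 10-18+8.5 = 0.5
  expect_equal(elbow_k(c(100, 10, 9, 8.5), 1:4), 2L)
  # single sharp kink at k = 3
  expect_equal(elbow_k(c(30, 20, 10, 9.5, 9), 1:5), 3L)
  # strictly linear decay has no elbow
  expect_warning(k <- elbow_k(c(10, 8, 6, 4), 1:4), "no elbow")
  expect_equal(k, 1L)
  expect_error(elbow_k(c(1, 2)), "at least 3")
  # ties resolve to the smallest k
  expect_equal(elbow_k(c(10, 6, 4, 0, -2), 1:5), 2L)
})

test_that("component-similarity saturation finds duplicated columns", {
  orth <- diag(4)
  dup <- cbind(diag(3), c(0, 0, 1))
  expect_equal(max_pairwise_cosine(dup), 1)
  res <- component_similarity_saturation(list(`4` = orth))
  expect_false(attr(res, "saturated"))
  expect_equal(as.integer(res), 4L)
  res2 <- component_similarity_saturation(list(`3` = diag(3), `4` = dup))
  expect_true(attr(res2, "saturated"))
  expect_equal(as.integer(res2), 4L)
})

test_that("scan_k populates all criteria and flags the true rank", {
  truth <- small_truth(seed = 9)
  dm <- cube_to_matrix(make_cube(truth))
  cfg <- unmixing_config(k = 2, max_iter = 400)
  scan <- scan_k(dm, 2:5, config = cfg, n_restarts = 4, seed = 2)
  expect_equal(scan$k, 2:5)
  expect_true(all(is.finite(scan$reconstruction_error)))
  expect_true(all(scan$dispersion >= 0 & scan$dispersion <= 1))
  # reconstruction error non-increasing in k (best-of-restarts)
  expect_true(all(diff(scan$reconstruction_error) <= 1e-6))
  ch <- attr(scan, "chosen")
  expect_equal(ch[["elbow"]], 3L)
  td <- tidy(scan)
  expect_true(all(c("chosen_elbow", "chosen_dispersion", "chosen_saturation")
                  %in% names(td)))
  # single-k scan passes through; empty range errors
  one <- scan_k(dm, 3, config = cfg, n_restarts = 2, seed = 2)
  expect_equal(nrow(one), 1L)
  expect_error(scan_k(dm, integer(0)), "empty")
})
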