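# Shared fixtures, all generated in code.

random_cube <- function(ny, nx, m, seed = 42) {
  set.seed(seed)
  hyper_cube(array(runif(ny * nx * m), c(ny, nx, m)))
}

# exactly rank-k non-negative matrix
rank_k_matrix <- function(m, n, k, seed = 1) {
  set.seed(seed)
  U <- matrix(runif(m * k, 0.1, 1), m, k)
  V <- matrix(runif(k * n, 0.1, 1), k, n)
  U %*% V
}

small_truth <- function(seed = 0, ...) {
  make_ground_truth(k = 3L, m = 60L, grid_shape = c(12L, 12L), seed = seed, ...)
}

final_objective <- function(fit) {
  fit$objective_trace[length(fit$objective_trace)]
}

expect_monotone_trace <- function(fit, tol = 1e-10) {
  tr <- fit$objective_trace
  if (length(tr) < 2) return(invisible(TRUE))
  expect_true(all(diff(tr) <= tol * pmax(abs(tr[-length(tr)]), 1e-12)),
              label = "objective trace non-increasing")
}
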