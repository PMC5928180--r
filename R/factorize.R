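#' Unmixing configuration
#'
#' Bundles every solver control: component count, similarity loss, soft
#' regularizer weights, hard constraints, initialization, and stopping rules.
#'
#' @param k number of endmembers (>= 1).
#' @param loss `"frobenius"` (default) or `"kl"` (generalized
#'   Kullback-Leibler, for count-like data; requires non-negative input).
#' @param lambda1 L1 weight on the abundances V (>= 0); drives insignificant
#'   abundances toward zero.
#' @param lambda2 spatial-smoothness weight (>= 0); penalizes abundance
#'   roughness across the edges of a pixel graph.
#' @param sum_to_one constrain every abundance column to the probability
#'   simplex (non-negative, summing to one), interpreting abundances as
#'   fractional spectral weights.
#' @param solver `"multiplicative"` (Lee-Seung style updates; objective is
#'   non-increasing) or `"hals"` (hierarchical alternating least squares,
#'   Frobenius loss only, faster per iteration).
#' @param init `"random"` (seeded uniform, scaled to the data magnitude) or
#'   `"nndsvd"` (deterministic SVD-based start).
#' @param seed RNG seed for random initialization and restarts.
#' @param tol relative objective-change stopping tolerance.
#' @param max_iter iteration cap.
#' @param literal_penalty use the raw `||V L V^T||_F^2` co-activation form of
#'   the spatial penalty instead of the default Laplacian roughness
#'   `tr(V L V^T)`; heuristic update, monotonicity not guaranteed.
#' @param eps denominator floor inside multiplicative updates.
#' @return An `unmixing_config` list.
#' @export
unmixing_config <- function(k, loss = c("frobenius", "kl"),
                            lambda1 = 0, lambda2 = 0, sum_to_one = FALSE,
                            solver = c("multiplicative", "hals"),
                            init = c("random", "nndsvd"),
                            seed = 1L, tol = 1e-6, max_iter = 500L,
                            literal_penalty = FALSE, eps = 1e-12) {
  loss <- match.arg(loss)
  solver <- match.arg(solver)
  init <- match.arg(init)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (lambda1 < 0) stop("lambda1 must be >= 0", call. = FALSE)
  if (lambda2 < 0) stop("lambda2 must be >= 0", call. = FALSE)
  if (solver == "hals" && loss != "frobenius")
    stop("hals solver supports the frobenius loss only", call. = FALSE)
  if (solver == "hals" && (lambda2 > 0 || sum_to_one))
    stop("hals supports lambda1 only; use the multiplicative solver for ",
         "spatial or sum-to-one constraints", call. = FALSE)
  structure(
    list(k = k, loss = loss, lambda1 = lambda1, lambda2 = lambda2,
         sum_to_one = isTRUE(sum_to_one), solver = solver, init = init,
         seed = as.integer(seed), tol = tol, max_iter = as.integer(max_iter),
         literal_penalty = isTRUE(literal_penalty), eps = eps),
    class = "unmixing_config"
  )
}

as_X <- function(dm) {
  if (inherits(dm, "data_matrix")) dm$X
  else if (inherits(dm, "sliding_fft_stack")) dm$features
  else as.matrix(dm)
}

dm_grid <- function(dm) {
  if (inherits(dm, "data_matrix") || inherits(dm, "sliding_fft_stack"))
    dm$grid_shape
  else c(1L, ncol(as.matrix(dm)))
}

new_factor_model <- function(U, V, config, method, objective_trace = numeric(0),
                             converged = NA, d = NULL, mu = NULL,
                             explained_variance = NULL, grid_shape = NULL,
                             channel_axis = NULL, warnings = character(0)) {
  structure(
    list(U = U, V = V, d = d, mu = mu,
         explained_variance = explained_variance,
         objective_trace = objective_trace, converged = converged,
         iterations = length(objective_trace), config = config,
         method = method, grid_shape = grid_shape,
         channel_axis = channel_axis, warnings = warnings),
    class = "factor_model"
  )
}

#' @export
#' @method print factor_model
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %s: %d channels x %d pixels, k = %d\n",
              x$method, nrow(x$U), ncol(x$V), ncol(x$U)))
  if (length(x$objective_trace))
    cat(sprintf("  objective %.6g after %d iterations (converged: %s)\n",
                x$objective_trace[length(x$objective_trace)],
                x$iterations, x$converged))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Factorization objective
#'
#' The configured similarity loss plus soft penalties:
#' Frobenius `||X - UV||_F^2` or generalized KL
#' `sum X log(X / UV) - X + UV` (with `0 log 0 = 0`), plus
#' `lambda1 * ||V||_1` and the spatial term — by default the Laplacian
#' roughness `lambda2 * tr(V L V^T)`, or `lambda2 * ||V W V^T||_F^2` under
#' the literal co-activation form.
#'
#' @param X data matrix (or [data_matrix()]). @param U,V factors.
#' @param config an [unmixing_config()]. @param graph optional
#'   [spatial_graph()] (required when `lambda2 > 0`).
#' @return Scalar objective value.
#' @export
unmix_objective <- function(X, U, V, config, graph = NULL) {
  X <- as_X(X)
  R <- U %*% V
  if (config$loss == "frobenius") {
    obj <- sum((X - R)^2)
  } else {
    pos <- X > 0
    obj <- sum(X[pos] * log(X[pos] / pmax(R[pos], config$eps))) - sum(X) + sum(R)
  }
  if (config$lambda1 > 0) obj <- obj + config$lambda1 * sum(abs(V))
  if (config$lambda2 > 0) {
    if (is.null(graph)) stop("lambda2 > 0 requires a graph", call. = FALSE)
    if (config$literal_penalty) {
      M <- as.matrix(V %*% graph$W %*% t(V))
      obj <- obj + config$lambda2 * sum(M^2)
    } else {
      obj <- obj + config$lambda2 * edge_roughness(V, graph)
    }
  }
  obj
}

# NNDSVD initialization (Boutsidis & Gallopoulos): deterministic non-negative
# start from the leading singular triplets.
nndsvd_init <- function(X, k, eps) {
  s <- svd(X, nu = k, nv = k)
  m <- nrow(X); n <- ncol(X)
  U <- matrix(0, m, k); V <- matrix(0, k, n)
  U[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  V[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      sig <- nup * nvp
      if (sig > 0) {
        U[, j] <- sqrt(s$d[j] * sig) * up / nup
        V[j, ] <- sqrt(s$d[j] * sig) * vp / nvp
      }
    } else {
      sig <- nun * nvn
      U[, j] <- sqrt(s$d[j] * sig) * un / nun
      V[j, ] <- sqrt(s$d[j] * sig) * vn / nvn
    }
  }
  mean_x <- mean(X)
  U[U < eps] <- mean_x * 1e-4 + eps
  V[V < eps] <- mean_x * 1e-4 + eps
  list(U = U, V = V)
}

init_factors <- function(X, config) {
  m <- nrow(X); n <- ncol(X); k <- config$k
  if (config$init == "nndsvd") return(nndsvd_init(X, k, config$eps))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(config$seed)
  sc <- sqrt(max(mean(X), config$eps) / k)
  out <- list(U = matrix(runif(m * k), m, k) * sc,
              V = matrix(runif(k * n), k, n) * sc)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

# scale columns of V by w (V %*% diag(w))
col_scale <- function(V, w) V * rep(w, each = nrow(V))

simplex_project_cols <- function(V, k, eps) {
  cs <- colSums(V)
  zero <- cs <= eps
  if (any(zero)) {
    V[, zero] <- 1 / k
    cs[zero] <- 1
  }
  list(V = col_scale(V, 1 / cs), n_zero = sum(zero))
}

#' Non-negative matrix factorization with physical constraints
#'
#' Factorizes a non-negative channels-by-pixels matrix X into endmember
#' spectra U (m x k) and abundances V (k x n) by minimizing the configured
#' loss (Frobenius or generalized KL) plus optional L1 sparsity on V,
#' spatial-smoothness regularization over a pixel graph, and a per-pixel
#' sum-to-one constraint. The default multiplicative solver has a
#' non-increasing objective trace; the sum-to-one variant interleaves a
#' simplex projection with the updates (the following U update re-absorbs the
#' scale).
#'
#' At exit, columns of U are normalized to unit L2 norm with the scales
#' folded into the rows of V (skipped under `sum_to_one`, where V is instead
#' left exactly on the simplex). The scale convention does not change the
#' reconstruction U V.
#'
#' @param dm a [data_matrix()], [sliding_fft()] stack, or bare non-negative
#'   matrix (channels x pixels).
#' @param config an [unmixing_config()].
#' @param graph a [spatial_graph()] over the same pixels; required when
#'   `config$lambda2 > 0`.
#' @return A `factor_model` with fields `U`, `V`, `objective_trace`,
#'   `converged`, `config`, and any solver warnings.
#' @examples
#' X <- outer(runif(20), runif(30))
#' fit <- nmf_unmix(X, unmixing_config(k = 1, seed = 1))
#' fit$converged
#' @export
nmf_unmix <- function(dm, config, graph = NULL) {
  X <- as_X(dm)
  if (any(X < 0)) stop("NMF requires a non-negative input matrix", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite entries in X", call. = FALSE)
  stopifnot(inherits(config, "unmixing_config"))
  m <- nrow(X); n <- ncol(X); k <- config$k
  warnings <- character(0)
  if (k >= min(m, n))
    warnings <- c(warnings, sprintf("k = %d >= min(m, n) = %d: factorization is not low-rank", k, min(m, n)))
  if (config$lambda2 > 0) {
    if (is.null(graph)) stop("lambda2 > 0 requires a graph", call. = FALSE)
    if (graph$n != n)
      stop("graph has ", graph$n, " pixels but X has ", n, call. = FALSE)
  }
  use_graph <- config$lambda2 > 0
  W <- if (use_graph) graph$W else NULL
  deg <- if (use_graph) graph$degree else NULL

  fac <- init_factors(X, config)
  U <- fac$U; V <- fac$V
  eps <- config$eps
  if (config$sum_to_one) V <- simplex_project_cols(V, k, eps)$V
  n_zero_total <- 0L

  trace <- numeric(config$max_iter)
  converged <- FALSE

  if (config$solver == "hals") {
    for (it in seq_len(config$max_iter)) {
      XVt <- tcrossprod(X, V); VVt <- tcrossprod(V)
      for (j in seq_len(k)) {
        u <- U[, j] + (XVt[, j] - U %*% VVt[, j]) / max(VVt[j, j], eps)
        u[u < 0] <- 0
        if (all(u == 0)) u <- rep(eps, m)
        U[, j] <- u
      }
      UtX <- crossprod(U, X); UtU <- crossprod(U)
      for (j in seq_len(k)) {
        v <- V[j, ] + (UtX[j, ] - UtU[j, ] %*% V - config$lambda1 / 2) /
          max(UtU[j, j], eps)
        v[v < 0] <- 0
        V[j, ] <- v
      }
      trace[it] <- unmix_objective(X, U, V, config, graph)
      if (it > 1 && abs(trace[it - 1] - trace[it]) <=
            config$tol * max(abs(trace[it - 1]), eps)) {
        converged <- TRUE; trace <- trace[seq_len(it)]; break
      }
    }
  } else {
    for (it in seq_len(config$max_iter)) {
      if (config$loss == "frobenius") {
        numV <- crossprod(U, X)
        denV <- crossprod(U) %*% V + config$lambda1 + eps
        if (use_graph) {
          if (config$literal_penalty) {
            P <- as.matrix(V %*% W)
            Mk <- P %*% t(V)
            denV <- denV + config$lambda2 * 4 * (Mk %*% P)
          } else {
            numV <- numV + config$lambda2 * as.matrix(V %*% W)
            denV <- denV + config$lambda2 * col_scale(V, deg)
          }
        }
        V <- V * numV / denV
        if (config$sum_to_one) {
          pr <- simplex_project_cols(V, k, eps)
          V <- pr$V; n_zero_total <- n_zero_total + pr$n_zero
        }
        numU <- tcrossprod(X, V)
        denU <- U %*% tcrossprod(V) + eps
        U <- U * numU / denU
      } else {
        R <- U %*% V + eps
        numV <- crossprod(U, X / R)
        denV <- colSums(U) + config$lambda1 + eps
        if (use_graph) {
          numV <- numV + config$lambda2 * as.matrix(V %*% W)
          V <- V * numV / (denV + config$lambda2 * col_scale(V, deg))
        } else {
          V <- V * numV / denV
        }
        if (config$sum_to_one) {
          pr <- simplex_project_cols(V, k, eps)
          V <- pr$V; n_zero_total <- n_zero_total + pr$n_zero
        }
        R <- U %*% V + eps
        numU <- (X / R) %*% t(V)
        U <- U * numU / rep(rowSums(V) + eps, each = m)
      }
      trace[it] <- unmix_objective(X, U, V, config, graph)
      if (it > 1 && abs(trace[it - 1] - trace[it]) <=
            config$tol * max(abs(trace[it - 1]), eps)) {
        converged <- TRUE; trace <- trace[seq_len(it)]; break
      }
    }
  }
  if (n_zero_total > 0)
    warnings <- c(warnings, sprintf(
      "%d all-zero abundance column(s) reset to uniform 1/k", n_zero_total))
  incr <- diff(trace)
  if (!config$sum_to_one && config$solver == "multiplicative" &&
      !config$literal_penalty &&
      any(incr > 1e-8 * pmax(abs(trace[-length(trace)]), eps)))
    warnings <- c(warnings, "objective trace increased beyond tolerance")

  if (config$sum_to_one) {
    pr <- simplex_project_cols(V, k, eps)  # exact simplex at exit
    V <- pr$V
  } else {
    s <- sqrt(colSums(U^2))
    pos <- s > eps
    U[, pos] <- col_scale(U[, pos, drop = FALSE], 1 / s[pos])
    V[pos, ] <- V[pos, , drop = FALSE] * s[pos]
  }

  new_factor_model(U, V, config, method = "nmf",
                   objective_trace = trace, converged = converged,
                   grid_shape = dm_grid(dm),
                   channel_axis = if (inherits(dm, "data_matrix")) dm$channel_axis,
                   warnings = warnings)
}

#' Count abundances below a significance floor
#'
#' Unconstrained NMF spends small abundance weight (e.g. a pixel split
#' 0.48 / 0.49 / 0.015 / 0.015 over four endmembers) to shave the objective;
#' entries below the floor are the ones L1 sparsity exists to suppress.
#'
#' @param v abundance vector or matrix. @param floor significance floor
#'   (default 0.05).
#' @return Number of entries strictly below the floor.
#' @export
count_insignificant <- function(v, floor = 0.05) sum(v < floor)

#' Truncated singular value decomposition
#'
#' Best rank-k approximation in the Frobenius norm (Eckart-Young):
#' `X ~ U diag(d) V` with orthonormal U columns and V rows and non-increasing
#' singular values.
#'
#' @param dm matrix or [data_matrix()]. @param k rank, `1 <= k <= min(m, n)`.
#' @return A `factor_model` with `U` (m x k), `d` (k singular values), and
#'   `V` (k x n, rows orthonormal; the abundance-style factor is `diag(d) V`).
#' @export
svd_truncated <- function(dm, k) {
  X <- as_X(dm)
  k <- as.integer(k)
  if (k < 1L || k > min(dim(X)))
    stop("k must lie in 1..min(m, n)", call. = FALSE)
  s <- svd(X, nu = k, nv = k)
  cfg <- unmixing_config(k = k)
  new_factor_model(s$u, t(s$v), cfg, method = "svd", d = s$d[seq_len(k)],
                   grid_shape = dm_grid(dm),
                   channel_axis = if (inherits(dm, "data_matrix")) dm$channel_axis)
}

#' Principal component analysis via SVD of the mean-centered matrix
#'
#' Centers every spectral channel (feature) at zero mean and takes the
#' truncated SVD; components are the top-k eigenvectors of the channel
#' covariance. Signs are fixed so each component's largest-magnitude
#' coordinate is positive.
#'
#' @param dm matrix or [data_matrix()] (channels x pixels).
#' @param k number of components.
#' @return A `factor_model` with `U` (loadings, m x k), `d` (singular values),
#'   `V` (k x n score directions), `mu` (channel means), and
#'   `explained_variance` (fraction per component).
#' @export
pca_unmix <- function(dm, k) {
  X <- as_X(dm)
  k <- as.integer(k)
  if (k < 1L || k > min(dim(X)))
    stop("k must lie in 1..min(m, n)", call. = FALSE)
  cen <- mean_center(X)
  s <- svd(cen$Xc, nu = k, nv = k)
  U <- s$u; V <- t(s$v)
  for (j in seq_len(k)) {      # sign convention
    i0 <- which.max(abs(U[, j]))
    if (U[i0, j] < 0) { U[, j] <- -U[, j]; V[j, ] <- -V[j, ] }
  }
  ev <- if (sum(s$d^2) > 0) s$d[seq_len(k)]^2 / sum(s$d^2) else rep(0, k)
  cfg <- unmixing_config(k = k)
  new_factor_model(U, V, cfg, method = "pca", d = s$d[seq_len(k)],
                   mu = cen$mu, explained_variance = ev,
                   grid_shape = dm_grid(dm),
                   channel_axis = if (inherits(dm, "data_matrix")) dm$channel_axis)
}

#' Reconstruct the data matrix from a fitted model
#' @param model a `factor_model`.
#' @return The reconstruction: `U V` for NMF, `U diag(d) V (+ mu)` for
#'   SVD/PCA.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  R <- switch(model$method,
    nmf = model$U %*% model$V,
    svd = model$U %*% (model$d * model$V),
    pca = model$U %*% (model$d * model$V) + model$mu,
    stop("unknown model method: ", model$method, call. = FALSE)
  )
  R
}

#' Per-pixel relative reconstruction error map
#'
#' Relative L2 error of each pixel's reconstructed spectrum, rendered on the
#' pixel grid — the per-pixel view of "compare real data with data restored
#' from the components".
#'
#' @param model a `factor_model`. @param dm the matrix it was fitted to.
#' @return `ny x nx` matrix of relative errors.
#' @export
residual_map <- function(model, dm) {
  X <- as_X(dm)
  R <- reconstruct(model)
  err <- sqrt(colSums((X - R)^2)) / (sqrt(colSums(X^2)) + model$config$eps)
  grid <- if (inherits(dm, "data_matrix") || inherits(dm, "sliding_fft_stack"))
    dm$grid_shape else model$grid_shape
  unclass(abundances_to_maps(err, grid))[, , 1]
}
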