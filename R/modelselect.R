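#' Consensus dispersion coefficient over random NMF restarts
#'
#' Runs NMF from `n_restarts` seeded random starts, assigns each pixel to its
#' dominant endmember (largest abundance; ties broken toward the lowest
#' index), and builds per-run connectivity matrices `C_ij = 1` iff pixels i
#' and j share a dominant endmember. The dispersion of the consensus
#' (averaged) connectivity,
#' `rho = (1/n^2) * sum_ij 4 * (Cbar_ij - 1/2)^2`,
#' lies in `[0, 1]`: 1 means the clustering is identical across restarts
#' (a well-supported k), values near 0 mean maximal instability.
#'
#' @param dm matrix or [data_matrix()]. @param k component count (`k < n`).
#' @param n_restarts number of random restarts (>= 2).
#' @param seed base seed; restart r uses `seed + r - 1`.
#' @param config optional template [unmixing_config()] whose loss/penalties
#'   are reused (k and seed are overridden per restart).
#' @return Scalar dispersion coefficient in `[0, 1]`.
#' @export
dispersion_coefficient <- function(dm, k, n_restarts = 20L, seed = 1L,
                                   config = NULL) {
  X <- as_X(dm)
  n <- ncol(X)
  if (k >= n) stop("k must be smaller than the pixel count", call. = FALSE)
  if (n_restarts < 2L) stop("n_restarts must be >= 2", call. = FALSE)
  labels <- matrix(0L, nrow = n_restarts, ncol = n)
  for (r in seq_len(n_restarts)) {
    cfg <- restart_config(config, k, seed + r - 1L)
    fit <- nmf_unmix(X, cfg)
    labels[r, ] <- dominant_endmember(fit$V)
  }
  consensus_dispersion(labels)
}

restart_config <- function(config, k, seed) {
  if (is.null(config)) return(unmixing_config(k = k, seed = seed, init = "random"))
  cfg <- unclass(config)
  cfg$k <- as.integer(k); cfg$seed <- as.integer(seed); cfg$init <- "random"
  do.call(unmixing_config, cfg[c("k", "loss", "lambda1", "lambda2",
                                 "sum_to_one", "solver", "init", "seed",
                                 "tol", "max_iter", "literal_penalty", "eps")])
}

#' Dominant endmember per pixel (ties toward the lowest index)
#' @param V `k x n` abundance matrix.
#' @return Integer vector of length n.
#' @export
dominant_endmember <- function(V) {
  max.col(t(V), ties.method = "first")
}

#' Dispersion of a consensus connectivity built from labelings
#' @param labels `r x n` integer matrix, one clustering per row.
#' @return Dispersion coefficient in `[0, 1]`.
#' @export
consensus_dispersion <- function(labels) {
  r <- nrow(labels); n <- ncol(labels)
  Cbar <- matrix(0, n, n)
  for (i in seq_len(r)) {
    li <- labels[i, ]
    Cbar <- Cbar + (outer(li, li, "==") * 1)
  }
  Cbar <- Cbar / r
  dispersion_of_consensus(Cbar)
}

#' Dispersion coefficient of a consensus matrix
#' @param Cbar `n x n` consensus connectivity with entries in `[0, 1]`.
#' @return `(1/n^2) * sum 4 * (Cbar - 1/2)^2`.
#' @export
dispersion_of_consensus <- function(Cbar) {
  mean(4 * (Cbar - 0.5)^2)
}

#' Elbow rank from a reconstruction-error curve
#'
#' Picks the k with maximal discrete curvature (second difference) of the
#' error-versus-k curve — the point of diminishing returns. Interior points
#' only; ties resolve to the smallest k. A curve with no curvature (strictly
#' linear decay) has no elbow: the smallest k is returned with a warning.
#'
#' @param errors reconstruction errors, one per k.
#' @param k_values the corresponding k's (default `seq_along(errors)`).
#' @return The chosen k (integer).
#' @export
elbow_k <- function(errors, k_values = seq_along(errors)) {
  if (length(errors) < 3L) stop("need at least 3 k values", call. = FALSE)
  if (length(errors) != length(k_values))
    stop("errors and k_values lengths differ", call. = FALSE)
  curv <- errors[-c(length(errors) - 1L, length(errors))] -
    2 * errors[-c(1L, length(errors))] +
    errors[-(1:2)]
  scale <- max(abs(errors), 1e-300)
  if (all(abs(curv) <= 1e-12 * scale)) {
    warning("no elbow: error curve has no curvature; returning smallest k")
    return(as.integer(k_values[1L]))
  }
  as.integer(k_values[-c(1L, length(k_values))][which.max(curv)])
}

#' First k at which fitted components begin to duplicate
#'
#' Beyond the true number of components, additional fitted endmembers start
#' to resemble existing ones. Reports the smallest scanned k whose endmember
#' matrix contains two columns with cosine similarity at or above the
#' threshold.
#'
#' @param U_by_k named list of endmember matrices, one per k (names = k).
#' @param threshold cosine threshold (default 0.95).
#' @return Integer k, with attribute `saturated` (FALSE when no k exceeded
#'   the threshold, in which case the largest scanned k is returned).
#' @export
component_similarity_saturation <- function(U_by_k, threshold = 0.95) {
  ks <- as.integer(names(U_by_k))
  if (any(is.na(ks))) ks <- seq_along(U_by_k)
  ord <- order(ks)
  for (i in ord) {
    if (max_pairwise_cosine(U_by_k[[i]]) >= threshold)
      return(structure(ks[i], saturated = TRUE))
  }
  structure(max(ks), saturated = FALSE)
}

#' Largest pairwise cosine among matrix columns
#' @param U matrix with >= 1 columns.
#' @return Max cosine over distinct column pairs (`-Inf` for < 2 columns).
#' @export
max_pairwise_cosine <- function(U) {
  k <- ncol(U)
  if (k < 2L) return(-Inf)
  nrm <- sqrt(colSums(U^2))
  nrm[nrm == 0] <- 1
  Un <- col_scale(U, 1 / nrm)
  G <- crossprod(Un)
  max(G[upper.tri(G)])
}

#' Scan candidate ranks with all three diagnostics
#'
#' For each k in `k_range`, fits NMF (best objective over `n_restarts` seeded
#' starts), and records the reconstruction error, the consensus dispersion
#' coefficient, and the running component-similarity saturation check.
#'
#' @param dm matrix or [data_matrix()]. @param k_range integer vector of
#'   candidate k (>= 1 value).
#' @param config template [unmixing_config()] (k/seed overridden).
#' @param n_restarts restarts per k for both the best fit and the consensus.
#' @param seed base seed. @param cosine_threshold saturation threshold.
#' @return A `rank_scan` object: tibble with columns `k`,
#'   `reconstruction_error` (relative Frobenius), `dispersion`, `max_cosine`,
#'   plus attributes `chosen` (named integer vector per criterion) and
#'   `models` (best fit per k).
#' @export
scan_k <- function(dm, k_range, config = NULL, n_restarts = 20L, seed = 1L,
                   cosine_threshold = 0.95) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 1L) stop("empty k_range", call. = FALSE)
  X <- as_X(dm)
  xnorm <- sqrt(sum(X^2))
  errs <- numeric(length(k_range))
  disp <- numeric(length(k_range))
  maxcos <- numeric(length(k_range))
  models <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    best <- NULL
    labels <- matrix(0L, nrow = n_restarts, ncol = ncol(X))
    for (r in seq_len(n_restarts)) {
      cfg <- restart_config(config, k, seed + r - 1L)
      fit <- nmf_unmix(dm, cfg)
      labels[r, ] <- dominant_endmember(fit$V)
      obj <- fit$objective_trace[length(fit$objective_trace)]
      if (is.null(best) || obj < best$obj) best <- list(fit = fit, obj = obj)
    }
    models[[i]] <- best$fit
    errs[i] <- sqrt(sum((X - reconstruct(best$fit))^2)) / xnorm
    disp[i] <- if (n_restarts >= 2) consensus_dispersion(labels) else NA_real_
    maxcos[i] <- max_pairwise_cosine(best$fit$U)
  }
  tab <- tibble::tibble(k = k_range, reconstruction_error = errs,
                        dispersion = disp, max_cosine = maxcos)
  chosen <- c(
    elbow = if (length(k_range) >= 3L)
      tryCatch(elbow_k(errs, k_range), warning = function(w) k_range[1L])
      else NA_integer_,
    dispersion = k_range[which.max(disp)],
    saturation = as.integer(component_similarity_saturation(
      setNames(lapply(models, `[[`, "U"), k_range), cosine_threshold))
  )
  structure(tab, chosen = chosen, models = setNames(models, k_range),
            class = c("rank_scan", class(tab)))
}

#' @export
#' @method print rank_scan
print.rank_scan <- function(x, ...) {
  NextMethod()
  ch <- attr(x, "chosen")
  cat("chosen k -- elbow:", ch[["elbow"]], " dispersion:", ch[["dispersion"]],
      " saturation:", ch[["saturation"]], "\n")
  invisible(x)
}
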