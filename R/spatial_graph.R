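#' Pixel-similarity graph
#'
#' A symmetric, zero-diagonal, non-negative similarity matrix W over the n
#' pixels, stored sparse, with its degree vector and graph Laplacian D - W.
#' The Laplacian's quadratic form measures abundance roughness across graph
#' edges and drives the spatial-smoothness regularizer.
#'
#' @param W symmetric non-negative matrix (dense or sparse) with zero diagonal.
#' @param scheme free-form construction descriptor.
#' @param grid_shape optional `c(ny, nx)` when the graph comes from a grid.
#' @return A `spatial_graph` with fields `W` (sparse `dgCMatrix`), `degree`,
#'   `scheme`, `grid_shape`, `n`.
#' @export
spatial_graph <- function(W, scheme = "custom", grid_shape = NULL) {
  W <- as(as(as(W, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  n <- nrow(W)
  if (n != ncol(W)) stop("W must be square", call. = FALSE)
  if (any(diag(W) != 0)) diag(W) <- 0
  if (!isSymmetric(W, tol = 1e-12))
    stop("W must be symmetric", call. = FALSE)
  if (any(W@x < 0)) stop("W must be non-negative", call. = FALSE)
  structure(
    list(W = W, degree = Matrix::rowSums(W), scheme = scheme,
         grid_shape = grid_shape, n = n),
    class = "spatial_graph"
  )
}

#' @export
#' @method print spatial_graph
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d pixels, %d edges, scheme: %s\n",
              x$n, length(x$W@x) / 2, x$scheme))
  invisible(x)
}

#' Grid-adjacency pixel graph
#'
#' Unit-weight graph connecting each pixel to its 4 (rook) or 8 (queen) grid
#' neighbours — the cheap default realization of "the mixture among
#' neighbouring pixels is likely to be similar".
#'
#' @param grid_shape integer `c(ny, nx)`.
#' @param connectivity 4 or 8.
#' @return A [spatial_graph()] over `ny * nx` pixels in raster order.
#' @export
build_grid_adjacency <- function(grid_shape, connectivity = 4) {
  grid_shape <- as.integer(grid_shape)
  ny <- grid_shape[1]; nx <- grid_shape[2]
  if (any(grid_shape < 1L)) stop("grid_shape components must be >= 1", call. = FALSE)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  idx <- raster_index(grid_shape)
  pid <- function(y, x) (y - 1L) * nx + x
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    y2 <- idx[, "y"] + o[1]; x2 <- idx[, "x"] + o[2]
    ok <- y2 >= 1L & y2 <= ny & x2 >= 1L & x2 <= nx
    from <- c(from, pid(idx[ok, "y"], idx[ok, "x"]))
    to <- c(to, pid(y2[ok], x2[ok]))
  }
  n <- ny * nx
  W <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                            dims = c(n, n))
  spatial_graph(W, scheme = paste0("grid", connectivity),
                grid_shape = grid_shape)
}

# median pairwise spectral distance over an evenly spaced pixel subsample
# (deterministic bandwidth heuristic; at most `cap` pixels)
median_pairwise_distance <- function(X, cap = 1000L) {
  n <- ncol(X)
  sub <- unique(as.integer(round(seq(1L, n, length.out = min(n, cap)))))
  d <- stats::dist(t(X[, sub, drop = FALSE]))
  stats::median(d)
}

#' Spectral-similarity pixel graph
#'
#' Gaussian kernel `exp(-d^2 / (2 sigma^2))` on pairwise Euclidean distances
#' between pixel spectra. For a 128 x 128-pixel dataset the dense similarity
#' matrix is 16384 x 16384, symmetric with zero diagonal; for anything that
#' size, set `knn` to keep only each pixel's strongest neighbours (computed in
#' column chunks, then symmetrized as `max(W, t(W))`).
#'
#' @param dm a [data_matrix()] (or bare channels x pixels matrix).
#' @param kernel_bandwidth Gaussian sigma; default is the median pairwise
#'   distance of an evenly spaced subsample of up to 1000 pixels.
#' @param knn keep only the `knn` largest similarities per pixel
#'   (`NULL` = dense).
#' @param chunk_size pixels per block in the chunked knn path.
#' @return A [spatial_graph()] with `scheme = "feature"`.
#' @export
build_feature_similarity <- function(dm, kernel_bandwidth = NULL, knn = NULL,
                                     chunk_size = 2048L) {
  X <- if (inherits(dm, "data_matrix")) dm$X else as.matrix(dm)
  grid_shape <- if (inherits(dm, "data_matrix")) dm$grid_shape else NULL
  if (!all(is.finite(X))) stop("non-finite features", call. = FALSE)
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 pixels", call. = FALSE)
  if (is.null(kernel_bandwidth)) kernel_bandwidth <- median_pairwise_distance(X)
  if (kernel_bandwidth <= 0) kernel_bandwidth <- 1
  sq <- colSums(X^2)
  if (is.null(knn)) {
    d2 <- outer(sq, sq, "+") - 2 * crossprod(X)
    d2[d2 < 0] <- 0
    W <- exp(-d2 / (2 * kernel_bandwidth^2))
    diag(W) <- 0
    W <- (W + t(W)) / 2  # kill asymmetric rounding noise
    return(spatial_graph(W, scheme = "feature", grid_shape = grid_shape))
  }
  knn <- as.integer(knn)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    blk <- s:e
    d2 <- outer(sq[blk], sq, "+") - 2 * crossprod(X[, blk, drop = FALSE], X)
    d2[d2 < 0] <- 0
    K <- exp(-d2 / (2 * kernel_bandwidth^2))
    K[cbind(seq_along(blk), blk)] <- 0
    for (r in seq_along(blk)) {
      ord <- order(K[r, ], decreasing = TRUE)[seq_len(min(knn, n - 1L))]
      keep <- ord[K[r, ord] > 0]
      ii <- c(ii, rep.int(blk[r], length(keep)))
      jj <- c(jj, keep)
      xx <- c(xx, K[r, keep])
    }
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Wt <- Matrix::t(W)
  W <- (W + Wt + abs(W - Wt)) / 2  # element-wise max, sparse-safe
  spatial_graph(W, scheme = sprintf("feature_knn%d", knn),
                grid_shape = grid_shape)
}

#' Graph Laplacian
#'
#' `L = D - W` with `D = diag(rowSums(W))`; row sums are zero and
#' `t(x) %*% L %*% x = 0.5 * sum_ij W_ij (x_i - x_j)^2`.
#'
#' @param graph a [spatial_graph()].
#' @return Sparse symmetric Laplacian matrix.
#' @export
graph_laplacian <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  Matrix::Diagonal(graph$n, graph$degree) - graph$W
}

#' Abundance roughness across graph edges
#'
#' `0.5 * sum_ij W_ij ||v_i - v_j||^2 = tr(V L V^T)` — the quantity the
#' spatial regularizer penalizes; useful for before/after comparisons.
#'
#' @param V `k x n` abundance matrix. @param graph a [spatial_graph()].
#' @return Scalar roughness.
#' @export
edge_roughness <- function(V, graph) {
  L <- graph_laplacian(graph)
  sum(diag(as.matrix(V %*% L %*% t(V))))
}

#' Export a graph as a coordinate-list table
#' @param graph a [spatial_graph()].
#' @return Tibble of upper-triangle edges `(i, j, weight)`.
#' @export
graph_edges <- function(graph) {
  T3 <- as(Matrix::triu(graph$W), "TsparseMatrix")
  tibble::tibble(i = T3@i + 1L, j = T3@j + 1L, weight = T3@x) |>
    dplyr::arrange(.data$i, .data$j)
}
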