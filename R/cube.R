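#' Hyperspectral cube container
#'
#' A gridded stack of spectra: `values[y, x, c]` holds channel `c` of the
#' pixel at grid row `y`, column `x`. The channel axis carries the physical
#' coordinate of each channel (mass-to-charge, energy, bias voltage,
#' momentum transfer) or plain labels.
#'
#' @param values numeric 3-d array `(ny, nx, m)`; a matrix is promoted to a
#'   single-channel cube.
#' @param channel_axis numeric or character vector of length `m`. Numeric
#'   axes must be strictly monotonic. Defaults to `1:m`.
#' @param meta named list of free-form provenance strings.
#' @return An object of class `hyper_cube` with fields `values`,
#'   `channel_axis`, `grid_shape` (`c(ny, nx)`), and `meta`.
#' @examples
#' cube <- hyper_cube(array(runif(2 * 3 * 4), c(2, 3, 4)))
#' dim(cube$values)
#' @export
hyper_cube <- function(values, channel_axis = NULL, meta = list()) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a (ny, nx, channels) array", call. = FALSE)
  d <- dim(values)
  if (any(d < 1L)) stop("empty cube: all dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(values)) stop("cube values must be numeric", call. = FALSE)
  m <- d[3L]
  if (is.null(channel_axis)) channel_axis <- seq_len(m)
  if (length(channel_axis) != m)
    stop("channel_axis length (", length(channel_axis),
         ") does not match channel count (", m, ")", call. = FALSE)
  if (is.numeric(channel_axis) && m > 1L) {
    dc <- diff(channel_axis)
    if (!(all(dc > 0) || all(dc < 0)))
      stop("numeric channel_axis must be strictly monotonic", call. = FALSE)
  }
  structure(
    list(values = values, channel_axis = channel_axis,
         grid_shape = d[1:2], meta = meta),
    class = "hyper_cube"
  )
}

#' @export
#' @method print hyper_cube
print.hyper_cube <- function(x, ...) {
  cat(sprintf("<hyper_cube> %d x %d pixels, %d channels\n",
              x$grid_shape[1], x$grid_shape[2], length(x$channel_axis)))
  if (length(x$meta)) cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Channel-by-pixel data matrix
#'
#' The factorization-ready view of a cube: `X` is `m x n` with m spectral
#' channels (features, rows) and n pixels (samples, columns). Column j holds
#' the full spectrum of pixel j under the package raster order (row-major,
#' y slow / x fast).
#'
#' @param X numeric matrix, `m x n`.
#' @param grid_shape integer `c(ny, nx)` with `ny * nx == ncol(X)`.
#' @param channel_axis per-channel coordinate, length `m` (default `1:m`).
#' @param meta named list of provenance strings.
#' @return An object of class `data_matrix` with fields `X`, `grid_shape`,
#'   `channel_axis`, `pixel_order = "row-major"`, `meta`.
#' @export
data_matrix <- function(X, grid_shape, channel_axis = NULL, meta = list()) {
  X <- as.matrix(X)
  if (!is.numeric(X) || nrow(X) < 1L || ncol(X) < 1L)
    stop("X must be a non-empty numeric matrix", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("grid_shape must be two positive integers (ny, nx)", call. = FALSE)
  if (prod(grid_shape) != ncol(X))
    stop("grid_shape (", grid_shape[1], " x ", grid_shape[2],
         ") does not match pixel count ", ncol(X), call. = FALSE)
  if (is.null(channel_axis)) channel_axis <- seq_len(nrow(X))
  if (length(channel_axis) != nrow(X))
    stop("channel_axis length must equal nrow(X)", call. = FALSE)
  structure(
    list(X = X, grid_shape = grid_shape, channel_axis = channel_axis,
         pixel_order = "row-major", meta = meta),
    class = "data_matrix"
  )
}

#' @export
#' @method print data_matrix
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d channels x %d pixels (grid %d x %d, %s)\n",
              nrow(x$X), ncol(x$X), x$grid_shape[1], x$grid_shape[2],
              x$pixel_order))
  invisible(x)
}

# Single raster-order contract for the whole package: pixel j (1-based) sits
# at grid row y = (j-1) %/% nx + 1, column x = (j-1) %% nx + 1.
raster_index <- function(grid_shape) {
  ny <- grid_shape[1]; nx <- grid_shape[2]
  j <- seq_len(ny * nx)
  cbind(y = (j - 1L) %/% nx + 1L, x = (j - 1L) %% nx + 1L)
}

#' Reshape a cube into a channel-by-pixel matrix
#'
#' Flattens the spatial grid in raster order (row-major, y slow / x fast) so
#' that a 128 x 128 grid with 1535 channels yields a 1535 x 16384 matrix whose
#' column j is the spectrum of pixel j.
#'
#' @param cube a [hyper_cube()].
#' @return A [data_matrix()].
#' @seealso [matrix_to_cube()] for the exact inverse.
#' @export
cube_to_matrix <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  # aperm to (channel, x, y): flattening column-major then gives column
  # index j = x + (y-1)*nx, i.e. the raster order above.
  X <- aperm(cube$values, c(3L, 2L, 1L))
  dim(X) <- c(d[3L], d[1L] * d[2L])  # reshape in place, no second copy
  data_matrix(X, grid_shape = d[1:2], channel_axis = cube$channel_axis,
              meta = cube$meta)
}

#' Reshape a channel-by-pixel matrix back into a cube
#'
#' Exact inverse of [cube_to_matrix()] under the package raster order.
#'
#' @param dm a [data_matrix()].
#' @return A [hyper_cube()].
#' @export
matrix_to_cube <- function(dm) {
  stopifnot(inherits(dm, "data_matrix"))
  ny <- dm$grid_shape[1]; nx <- dm$grid_shape[2]; m <- nrow(dm$X)
  values <- aperm(array(dm$X, dim = c(m, nx, ny)), c(3L, 2L, 1L))
  hyper_cube(values, channel_axis = dm$channel_axis, meta = dm$meta)
}

#' Render abundance rows as spatial maps
#'
#' Reshapes each row of a k x n abundance matrix onto the pixel grid under the
#' same raster order as [cube_to_matrix()].
#'
#' @param V numeric `k x n` abundance matrix (rows = endmembers).
#' @param grid_shape integer `c(ny, nx)` with `ny * nx == ncol(V)`.
#' @param endmember_ids optional labels, defaults to `"EM1"`, `"EM2"`, ...
#' @return An `abundance_maps` object: 3-d array `(ny, nx, k)` with the
#'   endmember labels on the third dimension.
#' @export
abundances_to_maps <- function(V, grid_shape, endmember_ids = NULL) {
  V <- rbind(V)  # promote a bare vector to a 1 x n matrix
  grid_shape <- as.integer(grid_shape)
  ny <- grid_shape[1]; nx <- grid_shape[2]
  if (ny * nx != ncol(V))
    stop("grid_shape does not match abundance pixel count", call. = FALSE)
  k <- nrow(V)
  if (is.null(endmember_ids)) endmember_ids <- paste0("EM", seq_len(k))
  # t(V) is n x k with pixels raster-ordered; fill x fastest then y.
  maps <- aperm(array(t(V), dim = c(nx, ny, k)), c(2L, 1L, 3L))
  dimnames(maps) <- list(NULL, NULL, endmember_ids)
  structure(maps, class = c("abundance_maps", "array"))
}

#' Flatten abundance maps back to a k x n matrix
#' @param maps an `abundance_maps` array `(ny, nx, k)`.
#' @return numeric `k x n` matrix in raster order.
#' @export
maps_to_abundances <- function(maps) {
  d <- dim(maps)
  t(matrix(aperm(unclass(maps), c(2L, 1L, 3L)), ncol = d[3L]))
}
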