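#' Center each spectral channel at zero mean
#'
#' Subtracts from every pixel the per-channel (feature) mean, the standard
#' PCA preprocessing step. The means are returned so the operation can be
#' inverted exactly.
#'
#' @param X numeric matrix, channels x pixels (a [data_matrix()]'s `X`).
#' @return A list with `Xc` (centered matrix, each row mean 0) and `mu`
#'   (per-channel mean vector).
#' @seealso [mean_uncenter()]
#' @export
mean_center <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric", call. = FALSE)
  mu <- rowMeans(X)
  list(Xc = X - mu, mu = mu)
}

#' Undo [mean_center()]
#' @param Xc centered matrix. @param mu per-channel means.
#' @return The original matrix.
#' @export
mean_uncenter <- function(Xc, mu) Xc + mu

#' Normalize a data matrix
#'
#' Global affine rescaling to a standard range, or a log transform for
#' count-like data. `"unit_interval"` maps the global minimum to 0 and
#' maximum to 1; `"symmetric_interval"` maps to `[-1, 1]`; `"log"` applies
#' `log1p` element-wise (offset 1 admits zero counts, as in mass spectra).
#'
#' @param X numeric matrix.
#' @param mode one of `"unit_interval"`, `"symmetric_interval"`, `"log"`.
#' @return A list with `Xn` (transformed matrix) and `record` — the step name
#'   and parameters sufficient to invert the interval modes exactly (see
#'   [denormalize()]).
#' @export
normalize <- function(X, mode = c("unit_interval", "symmetric_interval", "log")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop("X must be numeric without NA", call. = FALSE)
  if (mode == "log") {
    if (any(X < 0)) stop("log normalization requires X >= 0", call. = FALSE)
    return(list(Xn = log1p(X),
                record = list(step = "log", offset = 1)))
  }
  lo <- min(X); hi <- max(X)
  if (hi - lo <= 0)
    stop("degenerate scale: constant matrix cannot be interval-normalized",
         call. = FALSE)
  if (mode == "unit_interval") {
    Xn <- (X - lo) / (hi - lo)
  } else {
    Xn <- 2 * (X - lo) / (hi - lo) - 1
  }
  list(Xn = Xn, record = list(step = mode, lo = lo, hi = hi))
}

#' Invert [normalize()] from its record
#' @param Xn transformed matrix. @param record the `record` from [normalize()].
#' @return The original-scale matrix.
#' @export
denormalize <- function(Xn, record) {
  switch(record$step,
    log = expm1(Xn),
    unit_interval = Xn * (record$hi - record$lo) + record$lo,
    symmetric_interval = (Xn + 1) / 2 * (record$hi - record$lo) + record$lo,
    stop("unknown preprocessing record: ", record$step, call. = FALSE)
  )
}

#' Number of sliding-window positions along one axis
#' @param extent image extent in px. @param window window size. @param step step size.
#' @return `floor((extent - window) / step) + 1`.
#' @export
sliding_window_count <- function(extent, window, step) {
  as.integer((extent - window) %/% step + 1L)
}

# centered (fftshifted) index permutation for one axis of length n
fftshift_idx <- function(n) {
  h <- ceiling(n / 2)
  c((h + 1):n, 1:h)
}

#' Sliding-window FFT feature stack
#'
#' Scans a `w x w` window across a 2-d image in steps of `s` px (top-left
#' anchored, raster order, trailing pixels not covered by a full window are
#' dropped) and records for each position the fftshift-centered 2-d FFT
#' magnitude of the patch, flattened to a feature column. Applied to
#' atomically resolved STEM images, NMF on this stack separates local
#' structure factors (endmembers) from their loading maps.
#'
#' @param image numeric matrix `H x W` (grayscale image, rows = y).
#' @param window window size w in px, `w <= min(H, W)`.
#' @param step step size s in px, `s >= 1`.
#' @return A `sliding_fft_stack`: list with `features` (`w^2 x nw`
#'   non-negative magnitude matrix), `window_size`, `step`, `window_origins`
#'   (tibble of top-left `y`, `x` per window, raster order), and `grid_shape`
#'   (`c(nwy, nwx)`) so the stack drops straight into the factorization
#'   functions as a [data_matrix()].
#' @export
sliding_fft <- function(image, window, step = 1L) {
  image <- as.matrix(image)
  H <- nrow(image); W <- ncol(image)
  window <- as.integer(window); step <- as.integer(step)
  if (window > min(H, W))
    stop("window (", window, ") larger than image (", H, " x ", W, ")",
         call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  nwy <- sliding_window_count(H, window, step)
  nwx <- sliding_window_count(W, window, step)
  sy <- fftshift_idx(window); sx <- fftshift_idx(window)
  origins <- raster_index(c(nwy, nwx))
  oy <- (origins[, "y"] - 1L) * step + 1L
  ox <- (origins[, "x"] - 1L) * step + 1L
  feats <- matrix(0, nrow = window * window, ncol = nwy * nwx)
  for (j in seq_len(nwy * nwx)) {
    patch <- image[oy[j]:(oy[j] + window - 1L), ox[j]:(ox[j] + window - 1L)]
    mag <- Mod(stats::fft(patch))[sy, sx]
    feats[, j] <- as.vector(mag)
  }
  structure(
    list(features = feats, window_size = window, step = step,
         window_origins = tibble::tibble(y = oy, x = ox),
         grid_shape = c(nwy, nwx)),
    class = "sliding_fft_stack"
  )
}

#' @export
#' @method print sliding_fft_stack
print.sliding_fft_stack <- function(x, ...) {
  cat(sprintf(
    "<sliding_fft_stack> %d windows (%d x %d grid), window %d px, step %d px\n",
    ncol(x$features), x$grid_shape[1], x$grid_shape[2], x$window_size, x$step))
  invisible(x)
}

#' View a sliding-FFT stack as a data matrix
#' @param stack a `sliding_fft_stack`.
#' @return A [data_matrix()] over the window grid.
#' @export
stack_to_matrix <- function(stack) {
  stopifnot(inherits(stack, "sliding_fft_stack"))
  data_matrix(stack$features, grid_shape = stack$grid_shape,
              meta = list(source = "sliding_fft",
                          window = stack$window_size, step = stack$step))
}
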